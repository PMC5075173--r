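# Independent oracles and fixture helpers. Nothing here calls the package's
# charge or solver code: the oracle computes net charge by direct
# per-group summation and locates the pI by scanning a pH grid for the
# sign change of the (strictly decreasing) charge.

# direct Henderson-Hasselbalch summation; `v` is a named vector of pKa
# values (NTERM, CTERM, C, D, E, H, K, R, Y), NA = group absent.
# Vectorized over `ph`.
oracle_charge <- function(sequence, ph, v, nterm = TRUE, cterm = TRUE) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  cnt <- function(a) sum(ch == a)
  neg <- c(CTERM = as.numeric(cterm), C = cnt("C"), D = cnt("D"),
           E = cnt("E"), Y = cnt("Y"))
  pos <- c(NTERM = as.numeric(nterm), H = cnt("H"), K = cnt("K"),
           R = cnt("R"))
  z <- rep(0, length(ph))
  for (g in names(neg)) {
    if (!is.na(v[[g]]) && neg[[g]] > 0) {
      z <- z - neg[[g]] / (1 + 10^(v[[g]] - ph))
    }
  }
  for (g in names(pos)) {
    if (!is.na(v[[g]]) && pos[[g]] > 0) {
      z <- z + pos[[g]] / (1 + 10^(ph - v[[g]]))
    }
  }
  z
}

# exhaustive grid scan for the charge sign change at `step` resolution,
# hierarchical (coarse pass, then a full-resolution pass inside the coarse
# bracket); identical to a flat scan because the charge is strictly
# decreasing in pH. Returns the midpoint of the two straddling grid points.
oracle_grid_pi <- function(sequence, v, step = 1e-4, coarse = 0.01) {
  grid <- seq(0, 14, by = coarse)
  z <- oracle_charge(sequence, grid, v)
  i <- max(which(z > 0))
  stopifnot(i < length(grid))              # sign change must exist
  fine <- seq(grid[i], grid[i + 1], by = step)
  zf <- oracle_charge(sequence, fine, v)
  j <- max(which(zf > 0))
  (fine[j] + fine[j + 1]) / 2
}

# flat single-pass variant (slow; used once to validate the hierarchical one)
oracle_grid_pi_flat <- function(sequence, v, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  z <- oracle_charge(sequence, grid, v)
  i <- max(which(z > 0))
  (grid[i] + grid[i + 1]) / 2
}

# random sequence over the full 20-letter alphabet
random_aa_sequence <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# write a small annotated FASTA and return its path
write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
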