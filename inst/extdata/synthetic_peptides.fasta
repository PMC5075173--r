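>SYN00001|[2.96845566892358]
MFNVMFESSVDGICQTSGFGLFP
>SYN00002|[3.08157020059871, 3.26368695815221]
VMMFTADAPSY
>SYN00003|[4.30952504969454]
ETQFTEK
>SYN00004|[2.84997752330368]
NITVYDLVQIAQDWWT
>SYN00005|[11.5532371921530, 11.5006426623435]
TWPMNMKMFR
>SYN00006|[11.9774657102675]
SQGMYDRPQQMRWRAGRYFFGWQR
>SYN00007|[6.22920166542935]
DLVMINSMACNNSSSNAKWAIQA
>SYN00008|[6.48899490904530, 6.63372918991428]
WWWYLGTRQYQIDWSYWVFAI
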