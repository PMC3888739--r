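species,toxicant,reason
Salmo gairdneri,Roundup,no regression coefficients printed for this dataset
Poecilia reticulata,Methylbenzoate,no regression coefficients printed for this dataset
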