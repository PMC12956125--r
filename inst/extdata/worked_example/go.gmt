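GOX	synthetic process	G01	G02	G06
GOY	synthetic process	G03	G07	G08
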