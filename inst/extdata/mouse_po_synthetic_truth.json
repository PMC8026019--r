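{"lungs":3,"heart":2.5,"brain":0.8,"muscle":4.1,"adipose":0.7,"remainder":0.8,"stomach":3.2,"liver":5.5,"kidney_tissue":4.5,"enterocytes":4.6}
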