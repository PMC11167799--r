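file,rows,md5
table1_recoveries.csv,48,7a4c59d6e79ea789d59c48b475eb7a10
table2_mark_recapture.csv,6,54870e27b8cc07564ee3e3404739f1c0
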