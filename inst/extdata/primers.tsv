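name	sequence	orientation
MTD7.2F	ATTAGGAGCHCCHGAYATAGCATT	F
MTD9.2R	CAGGCAAGATTAAAATATAAACTTCTG	R
TCOR	ATTGCGTAAATTATTCCTAAAAGTCCA	R
TCOS	AACAGCTATTCTCCTTCTTTATCTC	F
TCOC	GAACAGTATATCCACCTTTATCAACG	F
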