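# SYNTHETIC observed-synthesis-fraction table for three fast-growing
# bacteria (ribosome-profiling-style proteome synthesis fractions).
# Constructed to match magnitudes and ratios reported for these factors in
# the literature (e.g. EF-Tu/EF-G of 3.9, 2.7 and 3.3 in E. coli,
# B. subtilis and V. natriegens respectively); NOT a transcription of any
# single published supplementary dataset. RFI is the RF1+RF2 sum.
species	factor	synthesis_fraction
E. coli	EF-Tu	0.0546
E. coli	ribosome	0.27
E. coli	EF-G	0.0140
E. coli	EF-Ts	0.0045
E. coli	aaRS	0.0140
E. coli	IF1	0.0008
E. coli	IF2	0.0015
E. coli	IF3	0.0009
E. coli	RF1	0.00024
E. coli	RF2	0.00041
E. coli	RFI	0.00065
E. coli	RF4	0.00050
B. subtilis	EF-Tu	0.0486
B. subtilis	ribosome	0.23
B. subtilis	EF-G	0.0180
B. subtilis	EF-Ts	0.0030
B. subtilis	aaRS	0.0120
B. subtilis	IF1	0.0006
B. subtilis	IF2	0.0013
B. subtilis	IF3	0.0008
B. subtilis	RF1	0.00030
B. subtilis	RF2	0.00040
B. subtilis	RFI	0.00070
B. subtilis	RF4	0.00060
V. natriegens	EF-Tu	0.0561
V. natriegens	ribosome	0.26
V. natriegens	EF-G	0.0170
V. natriegens	EF-Ts	0.0040
V. natriegens	aaRS	0.0130
V. natriegens	IF1	0.0007
V. natriegens	IF2	0.0014
V. natriegens	IF3	0.0008
V. natriegens	RF1	0.00025
V. natriegens	RF2	0.00040
V. natriegens	RFI	0.00065
V. natriegens	RF4	0.00045
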