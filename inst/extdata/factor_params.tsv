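# Per-factor biophysical parameters for the coarse-grained translation cycle.
# SYNTHETIC COMPILATION: protein lengths are standard E. coli values (UniProt);
# diffusion constants are representative in vivo single-molecule estimates
# (translating ribosome ~0.04 um^2/s, free subunits ~0.4 um^2/s, EF-Tu-sized
# proteins ~2 um^2/s); missing diffusion constants are estimated at load time
# by cube-root (Stokes-Einstein) scaling anchored on EF-Tu. The only measured
# association rate constant is the ternary-complex/ribosome anchor (6.4/uM/s);
# all other kon_hat values are estimated at load time by diffusion scaling.
# 'aaRS' is the coarse-grained lumped synthetase (length = typical synthetase).
# '50S' is the free large-subunit pool awaiting joining; its effective length
# is taken as the full ribosomal protein complement. Step 'reference' rows are
# species used only for diffusion lookups. Empty cell = absent; inf = no
# catalytic limit (binding-limited).
name	step	length_aa	diffusion_um2_s	kon_hat_uM_s	kcat_s	codon_specific	per_protein_uses
ribosome	reference	7300	0.04		inf	FALSE	1
ribosome30S	reference	2300	0.4		inf	FALSE	1
TC	reference	394	2.0	6.4	inf	TRUE	1
tRNA	reference	25	5.0		inf	FALSE	1
aatRNA	reference	25	5.0		inf	FALSE	1
IF1	initiation	72			inf	FALSE	1
IF2	initiation	890			inf	FALSE	1
IF3	initiation	180			inf	FALSE	1
50S	initiation	7300	0.4		inf	FALSE	1
EF-Tu	elongation	394	2.0		inf	TRUE	avg_len
EF-Ts	elongation	283			inf	FALSE	avg_len
EF-G	elongation	704			inf	FALSE	avg_len
aaRS	elongation	650			inf	TRUE	avg_len
RFI	termination	362			inf	FALSE	1
RF1	termination	360			inf	FALSE	1
RF2	termination	365			inf	FALSE	1
RF4	termination	185			inf	FALSE	1
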