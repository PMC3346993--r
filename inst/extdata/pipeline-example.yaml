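# Reproduces the synthetic plasma-determination study end to end:
# simulate the 16-sample cube (+3 blanks), estimate the chemical rank,
# decompose with both algorithms, predict concentrations and compute
# figures of merit.
seed: 1
outdir: trical-run
stages: [simulate, rank, decompose, calibrate, fom]
scan_range: [1, 2, 3, 4, 5]
algorithms: [parafac_als, swatld]
noise_sd: 0.005
baseline_offset: 0.0
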