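# clonedrift run configuration (YAML key = value)
# Experiment geometry -------------------------------------------------
bottleneck_size: 200    # founder cells sampled at the bottleneck
divisions: 15           # population doublings during expansion (13-17)
seq_error: 0.001        # per-base miscall probability (Q30 floor)
grid_size: 512          # frequency bins for the numeric kernels
diploid: false          # model cell fractions instead of allele fractions
# Multiple testing ----------------------------------------------------
target_bp: 290000       # Bonferroni denominator (target size in bp)
fwer: 0.05              # family-wise error rate
# Selection grid ------------------------------------------------------
s_step: 0.05            # grid spacing for s in [-1, 1]
# Variant screen ------------------------------------------------------
p_threshold: 0.01       # corrected p-value cutoff for a call
min_alt_count: 3        # minimum alternate reads for a call
hom_ref_frac: 0.98      # early-passage reference fraction for eligibility
# Synthetic data ------------------------------------------------------
n_sites: 290000         # simulated target positions
mean_depth: 1656        # mean per-site depth
depth_sdlog: 0.25       # log-normal depth dispersion
seed: 1
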