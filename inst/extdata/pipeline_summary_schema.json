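{
  "simulate": ["n_sites", "n_individuals", "model"],
  "qc": ["genotype_mask_counts", "site_filter_counts", "fp_snps",
         "fp_windows_blacklisted", "fp_discarded_fraction",
         "genome_removed_fraction", "snps_after_blacklist",
         "snps_after_thinning"],
  "stats": ["het_per_kb", "inbreeding_F", "kinship_max_offdiag",
            "pc1_varexp"],
  "sfs": ["joint_total", "syn_S", "nonsyn_S", "theta_w_syn", "pi_syn",
          "tajima_d_syn", "pin_pis"],
  "demography": ["models", "loglik", "AIC", "best_model", "best_params"],
  "dfe": ["shape", "mean_Nes", "bin_proportions"],
  "comparative": ["n_species", "regression_slope", "regression_intercept"]
}
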