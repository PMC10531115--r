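# The spike-detection experiment shared by unit and acceptance tests.
#
# World (fixed a priori): one 100 cM chromosome with 200 SNPs on a 0.5 cM
# grid, 50 diploid samples, 10 generations since admixture, posterior
# noise 0.02, mixing (IBS 0.35, YRI 0.35, NA 0.30); the spike boosts NA
# segments to 0.9 over [47.5, 52.5] cM, which contains exactly 10 grid
# SNPs — the target loci. Controls: 60 random loci outside the window.
spike_experiment_p <- function(rep_seed, spiked) {
  params <- simulation_params(mix = c(0.35, 0.35, 0.30), generations = 10,
                              n_samples = 50L,
                              chrom_lengths_cm = c("1" = 100),
                              n_snps = 200L, posterior_noise = 0.02,
                              seed = rep_seed)
  spikes <- if (spiked) list(enrichment_spike("1", 47.5, 52.5, "NA", 0.9))
  sim <- simulate_cohort(params, spikes)
  ls <- summarize_ancestry(concat_chromosomes(sim$posteriors))
  inwin <- ls$loci$cm > 47.5 & ls$loci$cm < 52.5
  stopifnot(sum(inwin) == 10L)
  targets <- subset_summary(ls, inwin)
  controls <- random_control(subset_summary(ls, !inwin), NULL,
                             n = 60L, seed = rep_seed + 1L)
  compare_enrichment(count_enriched(targets),
                     count_enriched(controls))$p_value
}
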