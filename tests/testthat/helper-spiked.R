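# Shared spiked-pair construction: two simulated families, a disease
# pathway planted in both affected twins, one family-private pathway per
# affected twin, and early-alphabet pathways planted in the unaffected
# twins.
spiked_pair <- function(seed1 = 11, seed2 = 22) {
  mkcfg <- function(seed, spikes) sim_config(
    seed = seed, n_chromosomes = 2, chromosome_length_bp = 2000000L,
    n_genes = 150, n_gene_sets = 30, genes_per_set = 4,
    n_inherited_snv = 400, n_inherited_indel = 40,
    n_inherited_blocksub = 8, n_germline_denovo = 4,
    n_somatic_per_twin = 8, n_cnv_shared = 20, n_cnv_unique = 0,
    n_sv_by_category = c(deletion = 10, interchromosomal = 4,
                         inversion = 2),
    n_sv_unique_per_twin = 0, spike = spikes)
  sp <- function(a1, a2, u1, u2) list(
    twin_affected = list(list(gene_set = a1, n_variants = 4),
                         list(gene_set = a2, n_variants = 4)),
    twin_unaffected = list(list(gene_set = u1, n_variants = 4),
                           list(gene_set = u2, n_variants = 4)))
  list(f1 = mkcfg(seed1, sp("pathway_30", "pathway_29",
                            "pathway_01", "pathway_02")),
       f2 = mkcfg(seed2, sp("pathway_30", "pathway_28",
                            "pathway_03", "pathway_04")))
}

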