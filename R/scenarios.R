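# Pre-configured scenarios.  Each builder fixes the study conditions the
# pipeline is validated under; amplitudes are expressed relative to the
# log-scale noise so separation statements ("2 x noise SD per signature
# feature") hold for any noise_sd.

# Signature feature sets used to build archetype directions.  Disjoint
# except where noted; none touches the five lineage totals, so planted
# shifts leave the normalisation denominator untouched.  Each set is split
# into an "up" and a "down" half so archetypes are compositionally balanced
# (zero net shift across the panel): an expansion of one compartment is
# mirrored by a contraction of its counterpart, as fractions demand, and the
# planted signal is orthogonal to the per-sample common mode.
.sig_sets <- function() {
  list(
    naive_core = list(
      up = c("Naive_CD4_T", "Naive_CD8_T", "Th1", "Th2"),
      down = c("Central_memory_CD4_T", "Memory_B", "CD56dim_NK",
               "Classical_monocytes")),
    treg_tfh = list(
      up = c("Th17", "Th1Th17", "Tfh"),
      down = c("Activated_Tfh", "Naive_Treg", "Memory_Treg")),
    activated_t = list(
      up = c("Effector_memory_CD4_T", "EMRA_CD4_T", "Activated_CD4_T",
             "Activated_CD8_T"),
      down = c("Central_memory_CD8_T", "Effector_memory_CD8_T",
               "EMRA_CD8_T", "CCR6_CD8_T")),
    b_subsets = list(
      up = c("Naive_B", "Switched_memory_B", "Transitional_B",
             "Plasmablasts"),
      down = c("Unswitched_memory_B", "Double_negative_B", "CD21low_B",
               "Activated_B")),
    innate_subsets = list(
      up = c("CD56bright_NK", "Activated_NK", "NKT_cells", "Myeloid_DCs"),
      down = c("Plasmacytoid_DCs", "Intermediate_monocytes",
               "Nonclassical_monocytes", "Gamma_delta_T"))
  )
}

.sig_plus <- function(set) set$up
.sig_minus <- function(set) set$down
.sig_all <- function(set) c(set$up, set$down)

.archetype_row <- function(cell_types, plus = character(), minus = character(),
                           amp = 0.7) {
  a <- stats::setNames(numeric(length(cell_types)), cell_types)
  a[plus] <- a[plus] + amp
  a[minus] <- a[minus] - amp
  a
}

#' Scenario with six planted patient archetypes
#'
#' Builds the patient-stratification validation scenario: reference-cohort
#' group sizes (947 samples over 11 AIRDs and controls), six planted patient
#' archetypes whose signature features are shifted by `2 * noise_sd`, and no
#' batch or confounder structure. Cluster proportions are 11/11/23/23/24/8
#' percent, identical in every disease group; the two 11 percent archetypes
#' are the closest pair (they differ in six features), so the admissibility
#' rule for patients (at least two clusters below 20 percent of the cohort)
#' is first met at exactly six clusters.
#'
#' @param noise_sd Log-scale noise SD (default 0.35).
#' @param separation Per-feature archetype shift in units of `noise_sd`
#'   (default 2).
#' @param n_per_group Named group sizes; defaults to the reference cohort.
#' @param seed Integer seed.
#' @return A [cohort_scenario()].
#' @export
scenario_patient_clusters <- function(noise_sd = 0.35, separation = 2,
                                      n_per_group = NULL, seed = 1L) {
  if (is.null(n_per_group)) n_per_group <- .reference_group_sizes()
  ct <- default_cell_panel()
  amp <- separation * noise_sd
  sig <- .sig_sets()
  arch <- rbind(
    c1 = .archetype_row(ct, plus = .sig_plus(sig$naive_core),
                        minus = .sig_minus(sig$naive_core), amp = amp),
    c2 = .archetype_row(ct,
                        plus = c(.sig_plus(sig$naive_core),
                                 .sig_plus(sig$treg_tfh)),
                        minus = c(.sig_minus(sig$naive_core),
                                  .sig_minus(sig$treg_tfh)), amp = amp),
    c3 = .archetype_row(ct, plus = .sig_plus(sig$activated_t),
                        minus = .sig_minus(sig$activated_t), amp = amp),
    c4 = .archetype_row(ct, plus = .sig_plus(sig$b_subsets),
                        minus = .sig_minus(sig$b_subsets), amp = amp),
    c5 = .archetype_row(ct, plus = .sig_plus(sig$innate_subsets),
                        minus = .sig_minus(sig$innate_subsets), amp = amp),
    c6 = .archetype_row(ct, plus = .sig_minus(sig$naive_core),
                        minus = .sig_plus(sig$naive_core), amp = amp)
  )
  cohort_scenario(
    n_per_group = n_per_group,
    patient_clusters = list(
      archetypes = arch,
      proportions = c(0.11, 0.11, 0.23, 0.23, 0.24, 0.08)
    ),
    noise_sd = noise_sd,
    seed = seed
  )
}

#' Scenario with four planted disease super-groups
#'
#' Twelve disease groups whose archetypes fall into four super-groups
#' mirroring the cross-disease structure seen in AIRD immunophenotyping
#' (SLE with MCTD; AAV with IIM and GCA; controls with SjS, SSc and IgG4RD;
#' AS with psoriasis and RA). Within each super-group one designated member
#' carries a larger disease-specific offset, so refining the four-cluster
#' partition always isolates a single disease first and the disease
#' admissibility rule (every cluster holds at least two diseases) selects
#' exactly four clusters.
#'
#' @param noise_sd Log-scale noise SD.
#' @param super_amp Per-feature shift of the super-group archetypes.
#' @param jitter,loose_jitter Disease-specific offsets on two dedicated
#'   features for tight and loose members respectively.
#' @param n_per_group Named group sizes; defaults to the reference cohort.
#' @param seed Integer seed.
#' @return A [cohort_scenario()] whose truth record carries the super-group
#'   map as `disease_supergroup`.
#' @export
scenario_disease_supergroups <- function(noise_sd = 0.35, super_amp = 0.5,
                                         jitter = 0.3, loose_jitter = 1.0,
                                         n_per_group = NULL, seed = 1L) {
  if (is.null(n_per_group)) n_per_group <- .reference_group_sizes()
  ct <- default_cell_panel()
  sig <- .sig_sets()
  supers <- list(
    sg1 = c("SLE", "MCTD"),
    sg2 = c("AAV", "IIM", "GCA"),
    sg3 = c("control", "SjS", "SSc", "IgG4RD"),
    sg4 = c("AS", "psoriasis", "RA")
  )
  loose <- c(sg1 = "MCTD", sg2 = "GCA", sg3 = "IgG4RD", sg4 = "AS")
  super_dir <- list(
    sg1 = .archetype_row(ct, plus = .sig_plus(sig$activated_t),
                         minus = .sig_minus(sig$activated_t), amp = super_amp),
    sg2 = .archetype_row(ct, plus = .sig_plus(sig$b_subsets),
                         minus = .sig_minus(sig$b_subsets), amp = super_amp),
    sg3 = .archetype_row(ct, plus = .sig_plus(sig$treg_tfh),
                         minus = .sig_minus(sig$treg_tfh), amp = super_amp),
    sg4 = .archetype_row(ct, plus = .sig_plus(sig$innate_subsets),
                         minus = .sig_minus(sig$innate_subsets),
                         amp = super_amp)
  )
  # two dedicated jitter features per disease, drawn from the unused core set
  jit_feats <- c(.sig_all(sig$naive_core),
                 c("Treg", "Activated_Treg", "CD8_T_cells", "Naive_B",
                   "Memory_Treg", "Activated_CD4_T", "NKT_cells",
                   "CD56bright_NK", "Myeloid_DCs", "Plasmacytoid_DCs",
                   "Intermediate_monocytes", "Nonclassical_monocytes",
                   "Transitional_B", "Double_negative_B", "Th17", "Th2"))
  diseases <- unlist(supers, use.names = FALSE)
  arch <- matrix(0, length(diseases), length(ct),
                 dimnames = list(diseases, ct))
  k <- 0L
  for (sg in names(supers)) {
    for (d in supers[[sg]]) {
      j <- if (d == loose[[sg]]) loose_jitter else jitter
      feats <- jit_feats[(2L * k + 1L):(2L * k + 2L)]
      arch[d, ] <- super_dir[[sg]]
      arch[d, feats] <- arch[d, feats] + j
      k <- k + 1L
    }
  }
  scen <- cohort_scenario(
    n_per_group = n_per_group[diseases],
    archetypes = arch,
    noise_sd = noise_sd,
    seed = seed
  )
  scen$disease_supergroup <- stats::setNames(
    rep(names(supers), lengths(supers)), diseases)
  scen
}

#' Scenario with six planted cell-type correlation blocks
#'
#' Block-correlated log-scale noise partitions the 46 cell types into six
#' biologically motivated correlation blocks (Treg/Tfh, activated T, B cells,
#' CD8 T, CD4/other T, innate). The B-cell block factor is moderately
#' correlated with the activated-T factor, mimicking the plasmablast /
#' activated-T covariation seen in peripheral blood, so that cuts below six
#' clusters mix the B and T lineages and the cell-type admissibility rule
#' first holds at six clusters.
#'
#' @param n Number of samples (single group).
#' @param noise_sd Log-scale noise SD.
#' @param within_r Within-block correlation (default 0.8).
#' @param cross_r Factor correlation between the B and activated-T blocks.
#' @param background_r Factor correlation between all other block pairs.
#' @param seed Integer seed.
#' @return A [cohort_scenario()] whose `correlation_blocks$blocks` is the
#'   planted block partition.
#' @export
scenario_celltype_blocks <- function(n = 300L, noise_sd = 0.35,
                                     within_r = 0.8, cross_r = 0.55,
                                     background_r = 0.1, seed = 1L) {
  blocks <- list(
    treg_tfh = c("Treg", "Naive_Treg", "Activated_Treg", "Memory_Treg",
                 "Tfh", "Activated_Tfh"),
    activated_t = c("Activated_CD4_T", "Activated_CD8_T", "CCR6_CD8_T",
                    "Th1Th17"),
    b_cells = c("B_cells", "Naive_B", "Memory_B", "Unswitched_memory_B",
                "Switched_memory_B", "Double_negative_B", "Transitional_B",
                "CD21low_B", "Activated_B", "Plasmablasts"),
    cd8_t = c("CD8_T_cells", "Naive_CD8_T", "Central_memory_CD8_T",
              "Effector_memory_CD8_T", "EMRA_CD8_T"),
    cd4_t = c("CD4_T_cells", "Naive_CD4_T", "Central_memory_CD4_T",
              "Effector_memory_CD4_T", "EMRA_CD4_T", "Th1", "Th2", "Th17",
              "Gamma_delta_T"),
    innate = c("NK_cells", "CD56bright_NK", "CD56dim_NK", "Activated_NK",
               "NKT_cells", "DCs", "Myeloid_DCs", "Plasmacytoid_DCs",
               "Monocytes", "Classical_monocytes", "Intermediate_monocytes",
               "Nonclassical_monocytes")
  )
  fc <- matrix(background_r, 6, 6, dimnames = list(names(blocks), names(blocks)))
  diag(fc) <- 1
  fc["activated_t", "b_cells"] <- cross_r
  fc["b_cells", "activated_t"] <- cross_r
  cohort_scenario(
    n_per_group = c(RA = as.integer(n)),
    noise_sd = noise_sd,
    correlation_blocks = list(blocks = blocks, within_r = within_r,
                              factor_cor = fc),
    seed = seed
  )
}

#' Full reference-style scenario
#'
#' The all-in scenario used for end-to-end pipeline runs: disease super-group
#' archetypes, six planted patient clusters, mild age/sex confounding, batch
#' shifts, a clinical layer with a planted treatment-response shift in one
#' cluster, and two PRS scores with planted clinical and dendritic-cell
#' effects.
#'
#' @param n_scale Multiplies every group size (values below 1 shrink the
#'   cohort for quick runs; sizes are kept at a minimum of 4).
#' @param noise_sd Log-scale noise SD.
#' @param seed Integer seed.
#' @return A [cohort_scenario()].
#' @export
scenario_reference_cohort <- function(n_scale = 1, noise_sd = 0.35, seed = 1L) {
  sizes <- .reference_group_sizes()
  sizes[] <- pmax(4L, as.integer(round(sizes * n_scale)))
  pat <- scenario_patient_clusters(noise_sd = noise_sd)
  dis <- scenario_disease_supergroups(noise_sd = noise_sd,
                                      n_per_group = sizes)
  ct <- default_cell_panel()
  batch_shift <- matrix(0, 4, length(ct), dimnames = list(NULL, ct))
  batch_shift[2, ] <- 0.10
  batch_shift[3, ] <- -0.10
  batch_shift[4, c("DCs", "Myeloid_DCs", "Plasmacytoid_DCs")] <- 0.2
  scen <- cohort_scenario(
    n_per_group = sizes,
    archetypes = dis$archetypes,
    patient_clusters = pat$patient_clusters,
    noise_sd = noise_sd,
    confounder_effects = list(
      age = c(Naive_CD4_T = -0.1, Naive_CD8_T = -0.1, EMRA_CD8_T = 0.08),
      sex = c(B_cells = 0.1, Naive_B = 0.1),
      batch = batch_shift
    ),
    clinical = list(
      cluster_effects = list(
        c1 = c(delta_EGA = -1.5),        # treatment-resistant cluster
        c4 = c(delta_EGA = 1.0, MTX_dose = 2.0)
      )
    ),
    prs = list(
      scores = c("prs_ra", "prs_ild"),
      effects = list(
        prs_ra = c(DAS28_CRP = 0.4, delta_EGA = -0.5),
        prs_ild = c(DCs = 0.1, Myeloid_DCs = 0.1, Plasmacytoid_DCs = 0.1)
      ),
      n_pcs = 10L
    ),
    seed = seed
  )
  scen$disease_supergroup <- dis$disease_supergroup
  scen
}
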