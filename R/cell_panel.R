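#' The default 46-type immunophenotype panel
#'
#' Column vocabulary used throughout the package: 46 immune cell subsets of
#' peripheral blood mononuclear cells (PBMCs), following the comprehensive
#' 8-colour flow-cytometry panels used in standardised human immunophenotyping.
#' Five columns are the major-lineage totals (CD4 T cells, B cells, NK cells,
#' dendritic cells, monocytes) whose per-sample sum defines the total viable
#' PBMC denominator used for normalisation.
#'
#' @return Character vector of length 46 with the cell-type names.
#' @seealso [lineage_map()], [lineage_totals()]
#' @export
default_cell_panel <- function() {
  names(.panel_base_fractions())
}

#' Major-lineage total columns
#'
#' The five columns whose sum is the total viable PBMC count: CD4 T cells,
#' B cells, NK cells, dendritic cells and monocytes.
#'
#' @return Character vector of length 5.
#' @export
lineage_totals <- function() {
  c("CD4_T_cells", "B_cells", "NK_cells", "DCs", "Monocytes")
}

#' Lineage classification of cell types
#'
#' Maps each cell type to one of the three major immune lineage classes
#' `"T"`, `"B"` or `"innate"`, used by the cell-type cluster-number
#' admissibility rule (clusters must not mix lineage classes). Plasmablasts
#' are assigned to the B lineage by ontogeny, even though their abundance
#' often co-varies with activated T cells.
#'
#' @param cell_types Character vector of cell-type names. Defaults to the
#'   full default panel.
#' @return Named character vector mapping cell type to lineage class.
#' @export
lineage_map <- function(cell_types = default_cell_panel()) {
  map <- .panel_lineages()
  unknown <- setdiff(cell_types, names(map))
  if (length(unknown) > 0L) {
    stop("no lineage assignment for cell type(s): ",
         paste(unknown, collapse = ", "))
  }
  map[cell_types]
}

# Baseline fractions (relative to the total viable PBMC denominator) used by
# the synthetic generator.  The five lineage totals sum to exactly 1 so the
# noiseless denominator equals the drawn total.
.panel_base_fractions <- function() {
  c(
    # T lineage -------------------------------------------------------------
    CD4_T_cells            = 0.45,
    CD8_T_cells            = 0.24,
    Naive_CD4_T            = 0.18,
    Central_memory_CD4_T   = 0.12,
    Effector_memory_CD4_T  = 0.08,
    EMRA_CD4_T             = 0.010,
    Naive_CD8_T            = 0.09,
    Central_memory_CD8_T   = 0.04,
    Effector_memory_CD8_T  = 0.06,
    EMRA_CD8_T             = 0.04,
    Th1                    = 0.06,
    Th2                    = 0.04,
    Th17                   = 0.03,
    Th1Th17                = 0.010,
    Tfh                    = 0.04,
    Activated_Tfh          = 0.008,
    Treg                   = 0.025,
    Naive_Treg             = 0.010,
    Activated_Treg         = 0.006,
    Memory_Treg            = 0.012,
    Activated_CD4_T        = 0.010,
    Activated_CD8_T        = 0.012,
    CCR6_CD8_T             = 0.015,
    Gamma_delta_T          = 0.03,
    # B lineage -------------------------------------------------------------
    B_cells                = 0.12,
    Naive_B                = 0.07,
    Memory_B               = 0.035,
    Unswitched_memory_B    = 0.015,
    Switched_memory_B      = 0.02,
    Double_negative_B      = 0.008,
    Transitional_B         = 0.004,
    Plasmablasts           = 0.003,
    CD21low_B              = 0.005,
    Activated_B            = 0.006,
    # innate lineage --------------------------------------------------------
    NK_cells               = 0.15,
    CD56bright_NK          = 0.010,
    CD56dim_NK             = 0.13,
    Activated_NK           = 0.012,
    NKT_cells              = 0.02,
    DCs                    = 0.03,
    Myeloid_DCs            = 0.012,
    Plasmacytoid_DCs       = 0.008,
    Monocytes              = 0.25,
    Classical_monocytes    = 0.20,
    Intermediate_monocytes = 0.02,
    Nonclassical_monocytes = 0.03
  )
}

.panel_lineages <- function() {
  fr <- .panel_base_fractions()
  nm <- names(fr)
  lin <- character(length(nm))
  names(lin) <- nm
  t_types <- nm[1:24]
  b_types <- nm[25:34]
  i_types <- nm[35:46]
  lin[t_types] <- "T"
  lin[b_types] <- "B"
  lin[i_types] <- "innate"
  lin
}

#' Disease-group vocabulary
#'
#' The 12 group labels (11 AIRDs plus healthy controls) recognised by the
#' pipeline.
#'
#' @return Character vector of length 12.
#' @export
disease_labels <- function() {
  c("RA", "SLE", "SSc", "AAV", "IIM", "psoriasis",
    "IgG4RD", "MCTD", "AS", "SjS", "GCA", "control")
}

# Post-QC group sizes of the reference cohort (947 samples in total).
.reference_group_sizes <- function() {
  c(RA = 285L, SLE = 170L, SSc = 131L, AAV = 94L, IIM = 77L,
    psoriasis = 35L, IgG4RD = 35L, MCTD = 22L, AS = 13L, SjS = 20L,
    GCA = 11L, control = 54L)
}
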