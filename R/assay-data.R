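#' Hepatocyte fold-induction assay data
#'
#' Mean fold increases (over vehicle) in CYP and P-gp mRNA after treating
#' cultured human hepatocytes with enzalutamide, its metabolites M1 and
#' N-desmethyl enzalutamide (M2), and prototypical inducers (omeprazole,
#' phenobarbital, rifampicin). Means and SDs are over hepatocyte lots
#' (`n_lots`; the 100 umol/L enzalutamide and M2 rows come from two lots,
#' all others from three).
#'
#' @param file Optional path to a CSV with the same layout; defaults to the
#'   packaged assay transcription.
#' @return A data.frame with columns `compound`, `gene`,
#'   `concentration_umol_L`, `fold_mean`, `fold_sd`, `n_lots`.
#' @seealso [fit_fold_induction()], [calibrate_indmax()]
#' @export
induction_table <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "hepatocyte_induction.csv",
                        package = "enzddi", mustWork = TRUE)
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_induction_table(d)
  d
}

validate_induction_table <- function(d) {
  need <- c("compound", "gene", "concentration_umol_L", "fold_mean",
            "fold_sd", "n_lots")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("induction table is missing columns: ", paste(miss, collapse = ", "))
  if (any(d$concentration_umol_L < 0)) stop("concentrations must be >= 0")
  if (any(d$fold_mean <= 0)) stop("fold_mean must be > 0")
  if (any(d$n_lots < 1)) stop("n_lots must be >= 1")
  invisible(d)
}

#' Bidirectional transwell permeability data
#'
#' Apparent permeability (P_app) of 1 umol/L 3H-digoxin across control and
#' MDR1-expressing LLC-PK1 cell monolayers in the apical-to-basal (`A2B`)
#' and basal-to-apical (`B2A`) directions, in the presence of increasing
#' concentrations of enzalutamide, M1, or M2.
#'
#' @param file Optional path to a CSV with the same layout; defaults to the
#'   packaged assay transcription.
#' @return A data.frame with columns `cell_line` (`control`/`MDR1`),
#'   `additive`, `additive_conc_umol_L`, `direction` (`A2B`/`B2A`),
#'   `papp_1e6_cm_s`, `papp_sd_1e6_cm_s`.
#' @seealso [summarize_efflux()], [fit_pgp_inhibition()]
#' @export
transwell_table <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "transwell_papp.csv",
                        package = "enzddi", mustWork = TRUE)
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  validate_transwell_table(d)
  d
}

validate_transwell_table <- function(d) {
  need <- c("cell_line", "additive", "additive_conc_umol_L", "direction",
            "papp_1e6_cm_s")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("transwell table is missing columns: ", paste(miss, collapse = ", "))
  if (!all(d$cell_line %in% c("control", "MDR1")))
    stop("cell_line must be 'control' or 'MDR1'")
  if (!all(d$direction %in% c("A2B", "B2A")))
    stop("direction must be 'A2B' or 'B2A'")
  if (any(d$papp_1e6_cm_s <= 0)) stop("papp must be > 0")
  if (any(d$additive_conc_umol_L < 0)) stop("additive_conc must be >= 0")
  invisible(d)
}
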