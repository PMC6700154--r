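#' Fit membrane statistical potentials and a residue-localization model
#'
#' The one-stop fitting function: from a set of structures with
#' resolved TM/EM region labels it (1) accumulates regional pair
#' counts, (2) derives the four smoothed, threshold-guarded
#' distance potentials (sd/sds for TM and EM), (3) computes every
#' residue's four folding-energy features under leave-one-out
#' potentials (each protein scored with its own contribution removed)
#' and (4) fits the seven-parameter localization model (linear index
#' over the four energies plus log-length and intercept, thresholded
#' after five-residue chain smoothing).
#'
#' @param structures list of `labeled_structure` objects with regions
#'   resolved (use [parse_structure()] + [assign_regions()], or the
#'   synthetic generator).
#' @param kBT Boltzmann factor in kcal/mol.
#' @param threshold occurrence guard for the potentials.
#' @param threshold_on `"smoothed"` or `"raw"`.
#' @param inter_chain pairing policy for counting and energies.
#' @param loo_features compute training features under per-protein
#'   leave-one-out potentials (slower, strict); with `FALSE` all
#'   features come from the full-dataset potentials.
#' @param seed integer seed recorded into the model.
#' @return an object of class `mempot`: list with `potentials`
#'   (the four full-dataset tables), `counts` (raw pooled TM/EM
#'   counts with per-protein sub-counts), `model`
#'   (`localization_model`), `features` (training feature table) and
#'   call metadata.  Methods: `print`, `summary`, `coef`, `predict`,
#'   `plot`.
#' @examples
#' set.seed(1)
#' gen <- generate_structures(fixture_config(n_proteins = 6), seed = 7)
#' fit <- mempot(lapply(gen, `[[`, "structure"), loo_features = FALSE)
#' coef(fit)
#' @export
mempot <- function(structures, kBT = 0.5925, threshold = 10,
                   threshold_on = "raw", inter_chain = FALSE,
                   loo_features = TRUE, seed = 1L) {
  ids <- vapply(structures, function(s) s$structure_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate structure ids")
  names(structures) <- ids
  counts <- list(TM = accumulate_pair_counts(structures, "TM",
                                             inter_chain = inter_chain),
                 EM = accumulate_pair_counts(structures, "EM",
                                             inter_chain = inter_chain))
  full_tables <- list(
    sd_TM = derive_potential(smooth_counts(counts$TM), "sd", kBT,
                             threshold, threshold_on),
    sds_TM = derive_potential(smooth_counts(counts$TM), "sds", kBT,
                              threshold, threshold_on),
    sd_EM = derive_potential(smooth_counts(counts$EM), "sd", kBT,
                             threshold, threshold_on),
    sds_EM = derive_potential(smooth_counts(counts$EM), "sds", kBT,
                              threshold, threshold_on))
  feats <- lapply(ids, function(id) {
    tabs <- if (loo_features) list(
      sd_TM = loo_potentials(counts$TM, id, "sd", kBT, threshold, threshold_on),
      sds_TM = loo_potentials(counts$TM, id, "sds", kBT, threshold, threshold_on),
      sd_EM = loo_potentials(counts$EM, id, "sd", kBT, threshold, threshold_on),
      sds_EM = loo_potentials(counts$EM, id, "sds", kBT, threshold, threshold_on))
    else full_tables
    prof <- per_residue_energies(structures[[id]], tabs,
                                 inter_chain = inter_chain)
    data.frame(structure_id = id, chain = prof$chain,
               seq_index = prof$seq_index, aa = prof$aa,
               truth = prof$region,
               dG_sd_TM = prof$dG_sd_TM, dG_sds_TM = prof$dG_sds_TM,
               dG_sd_EM = prof$dG_sd_EM, dG_sds_EM = prof$dG_sds_EM,
               log_N = log(nrow(prof)), stringsAsFactors = FALSE)
  })
  features <- do.call(rbind, feats)
  model <- fit_localization_model(features, features$truth, seed = seed)
  out <- structure(list(potentials = full_tables, counts = counts,
                        model = model, features = features,
                        options = list(kBT = kBT, threshold = threshold,
                                       threshold_on = threshold_on,
                                       inter_chain = inter_chain,
                                       loo_features = loo_features,
                                       seed = seed,
                                       n_structures = length(structures))),
                   class = "mempot")
  out
}

#' @export
print.mempot <- function(x, ...) {
  cat("Membrane statistical-potential model\n")
  cat("  fitted on ", x$options$n_structures, " structures (",
      nrow(x$features), " residues; ",
      sum(x$features$truth == "TM"), " TM / ",
      sum(x$features$truth == "EM"), " EM)\n", sep = "")
  cat("  kBT = ", x$options$kBT, " kcal/mol, occurrence threshold ",
      x$options$threshold, " on ", x$options$threshold_on,
      " counts\n", sep = "")
  print(x$model)
  invisible(x)
}

#' @export
summary.mempot <- function(object, ...) {
  sc <- model_scores(object$model, object$features)
  ev <- classify_and_evaluate(sc$I_sm, object$features$truth,
                              object$model$a0)
  cat("Training (resubstitution) performance:\n")
  print(ev)
  for (nm in names(object$potentials)) {
    p <- object$potentials[[nm]]
    cat(sprintf("  potential %-7s %4d/%4d unmasked bins\n", nm,
                sum(!p$mask), length(p$mask)))
  }
  invisible(list(evaluation = ev, model = object$model))
}

#' @export
coef.mempot <- function(object, ...) coef(object$model)

#' Classify the residues of a new structure
#'
#' Computes the structure's per-residue energies under the fitted
#' full-dataset potentials, the raw and smoothed localization index,
#' and the TM/EM call at the fitted threshold.
#'
#' @param object a fitted `mempot` model.
#' @param structure a `labeled_structure` (region labels are not
#'   used for prediction; if present they are carried through for
#'   comparison).
#' @param ... unused.
#' @return data frame with chain, seq_index, aa, the four energies,
#'   `I`, `I_sm` and `call`.
#' @export
predict.mempot <- function(object, structure, ...) {
  prof <- per_residue_energies(structure, object$potentials,
                               inter_chain = object$options$inter_chain)
  feats <- data.frame(structure_id = structure$structure_id,
                      chain = prof$chain,
                      dG_sd_TM = prof$dG_sd_TM, dG_sds_TM = prof$dG_sds_TM,
                      dG_sd_EM = prof$dG_sd_EM, dG_sds_EM = prof$dG_sds_EM,
                      log_N = log(nrow(prof)))
  sc <- model_scores(object$model, feats)
  data.frame(chain = prof$chain, seq_index = prof$seq_index, aa = prof$aa,
             region = prof$region,
             dG_sd_TM = prof$dG_sd_TM, dG_sds_TM = prof$dG_sds_TM,
             dG_sd_EM = prof$dG_sd_EM, dG_sds_EM = prof$dG_sds_EM,
             I = sc$I, I_sm = sc$I_sm,
             call = ifelse(sc$I_sm <= object$model$a0, "TM", "EM"),
             stringsAsFactors = FALSE)
}

#' @export
plot.mempot <- function(x, what = c("index", "potential"),
                        structure = NULL, pair = c("LEU", "LEU"),
                        region = "TM", flavor = "sds", ...) {
  what <- match.arg(what)
  if (what == "potential") {
    plot(x$potentials[[paste0(flavor, "_", region)]], pair = pair, ...)
  } else {
    if (is.null(structure)) stop("supply a structure to plot its index profile")
    pr <- predict(x, structure)
    graphics::plot(seq_len(nrow(pr)), pr$I_sm, type = "l",
                   xlab = "residue", ylab = expression(I[sm]), ...)
    graphics::abline(h = x$model$a0, lty = 2, col = 2)
    tm <- pr$region == "TM"
    if (any(tm)) graphics::rug(which(tm), col = 2)
  }
  invisible(x)
}
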