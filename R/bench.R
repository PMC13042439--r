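# Model-vs-reference comparison and reporting: signed deviation tables
# (model minus reference, the parenthetical convention of published QM/MM
# region benchmarks) and rank agreement between computed energies and
# experimental activities.

#' Deviation table of region models against a reference model
#'
#' @param values Either a tibble with columns `model`, `label`, `value`, or
#'   a named list of named vectors/lists (`values[[model]][[label]]`).
#' @param reference_model Name of the reference model (must cover every
#'   label).
#' @param units Unit string recorded on the table.
#' @return A `deviation_table` tibble with `label`, `model`, `value`,
#'   `reference`, `deviation` (= value - reference; missing model values are
#'   kept as explicit `NA` gaps).
#' @export
model_comparison <- function(values, reference_model, units = "") {
  if (!is.data.frame(values)) {
    values <- purrr::imap_dfr(values, function(v, m) {
      tibble::tibble(model = m, label = names(v),
                     value = as.numeric(unlist(v)))
    })
  }
  values <- tibble::as_tibble(values)
  need <- c("model", "label", "value")
  miss <- setdiff(need, names(values))
  if (length(miss) > 0) {
    rlang::abort(paste0("values table misses columns: ",
                        paste(miss, collapse = ", ")))
  }
  if (!reference_model %in% values$model) {
    rlang::abort(sprintf("reference model '%s' absent", reference_model))
  }
  ref <- values[values$model == reference_model, c("label", "value")]
  labels <- unique(values$label)
  if (!all(labels %in% ref$label)) {
    rlang::abort(sprintf("reference model misses label(s): %s",
                         paste(setdiff(labels, ref$label), collapse = ", ")))
  }
  models <- unique(values$model)
  grid <- tidyr::expand_grid(label = labels, model = models)
  out <- dplyr::left_join(grid, values, by = c("label", "model"))
  out <- dplyr::left_join(out, dplyr::rename(ref, reference = "value"),
                          by = "label")
  out$deviation <- out$value - out$reference
  class(out) <- c("deviation_table", class(tibble::tibble()))
  attr(out, "reference_model") <- reference_model
  attr(out, "units") <- units
  attr(out, "model_order") <- models
  out
}

#' @export
print.deviation_table <- function(x, ...) {
  ref <- attr(x, "reference_model")
  units <- attr(x, "units")
  cat(sprintf("<deviation_table> reference '%s'%s\n", ref,
              if (nzchar(units)) paste0(" [", units, "]") else ""))
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(x)[, c("label", "model", "value", "deviation")],
    names_from = "model", values_from = c("value", "deviation"))
  for (lb in unique(x$label)) {
    sub <- x[x$label == lb, ]
    vals <- sprintf("%8.1f", sub$value)
    vals[is.na(sub$value)] <- "      --"
    devs <- sprintf("(%+.1f)", sub$deviation)
    devs[is.na(sub$deviation) | sub$model == ref] <- ""
    cat(sprintf("  %-6s %s\n", lb,
                paste(sprintf("%s %-8s", vals, devs), collapse = " ")))
  }
  cat("  models:", paste(attr(x, "model_order"), collapse = "  "), "\n")
  invisible(wide)
}

#' Serialize a deviation table as TSV
#'
#' @param table A `deviation_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deviation_table <- function(table, path) {
  utils::write.table(tibble::as_tibble(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank agreement between computed values and experimental activities
#'
#' Rank-correlation coefficient (Spearman or Kendall, average-rank ties)
#' between the computed column and the experimental activity column of an
#' activity series.
#'
#' @param series Tibble with columns `label`, `activity` (e.g. pIC50) and
#'   `computed` (e.g. binding energy in kcal/mol).
#' @param method `"spearman"` or `"kendall"`.
#' @return The coefficient, in `[-1, 1]`.
#' @export
rank_agreement <- function(series, method = c("spearman", "kendall")) {
  method <- match.arg(method)
  series <- tibble::as_tibble(series)
  need <- c("label", "activity", "computed")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0) {
    rlang::abort(paste0("series misses columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(series$label) > 0) rlang::abort("labels must be unique")
  if (nrow(series) < 3) rlang::abort("need at least 3 observations")
  if (anyNA(series$activity) || anyNA(series$computed)) {
    rlang::abort("missing values in activity series")
  }
  if (stats::sd(series$activity) == 0 || stats::sd(series$computed) == 0) {
    rlang::abort("constant column: rank correlation undefined")
  }
  stats::cor(series$activity, series$computed, method = method)
}

#' Published FMO-DFTB benchmark tables for the validation systems
#'
#' Reference values distributed with the package for the two validation
#' systems: the CHA zeolite-OSDA complex (QM-atom counts and guest IP/EA per
#' region model) and the cathepsin L inhibitor series (binding energies per
#' region model, PIEDA components, experimental pIC50). Used by the
#' benchmark helpers and the acceptance script; energies in kcal/mol,
#' orbital properties in eV.
#'
#' @return A named list of tibbles: `osda_ip_ea`, `cathepsin_binding`,
#'   `cathepsin_pieda`, `cathepsin_pic50`.
#' @export
benchmark_tables <- function() {
  dir <- system.file("extdata", "benchmarks", package = "qmregion")
  rd <- function(f) tibble::as_tibble(utils::read.delim(file.path(dir, f),
                                                        check.names = FALSE))
  list(
    osda_ip_ea = rd("osda_ip_ea.tsv"),
    cathepsin_binding = rd("cathepsin_binding.tsv"),
    cathepsin_pieda = rd("cathepsin_pieda.tsv"),
    cathepsin_pic50 = rd("cathepsin_pic50.tsv")
  )
}
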