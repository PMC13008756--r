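# Readers/writers for the pipeline's file formats: indicator-tree JSON,
# panel and ratings CSV, and JSON/markdown reports. CSVs are comma-separated
# UTF-8 with a header row; all numbers use a decimal point regardless of
# locale. Rounding (2 d.p. scores, 3 d.p. weights and fit indices, half-up)
# happens only at the report layer; persisted values keep full precision.

#' Load an indicator tree from JSON
#'
#' @param path path to a tree JSON file (fields `round_tag`, `indicators`).
#' @return an `indicator_tree`.
#' @export
load_tree <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  ind <- tibble::as_tibble(obj$indicators)
  tree <- indicator_tree(ind, round_tag = obj$round_tag %||% "")
  viol <- validate_tree(tree)
  if (nrow(viol) > 0) {
    stop("invalid indicator tree in ", path, ": ",
         paste(sprintf("%s [%s]", viol$id, viol$rule), collapse = "; "),
         call. = FALSE)
  }
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save an indicator tree to JSON
#'
#' Writes a canonical JSON serialisation; save -> load -> save is
#' byte-stable.
#'
#' @param tree an `indicator_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_tree <- function(tree, path) {
  obj <- list(round_tag = tree$round_tag,
              indicators = as.data.frame(tree$indicators))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Load a long-form ratings CSV
#'
#' Required columns: `expert_id`, `indicator_id`, `round`, `rating`. Ratings
#' must be integers in 0..10 (0 = deletion vote); duplicate
#' (expert, indicator, round) keys are rejected with their row numbers.
#'
#' @param path CSV path.
#' @return rating tibble.
#' @export
load_ratings <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "indicator_id", "round", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("ratings CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$rating) | df$rating %% 1 != 0 |
                 df$rating < 0 | df$rating > 10)
  if (length(bad) > 0) {
    stop("out-of-range rating at row(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  dup <- which(duplicated(df[, c("expert_id", "indicator_id", "round")]))
  if (length(dup) > 0) {
    stop("duplicate (expert, indicator, round) at row(s): ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(expert_id = as.character(df$expert_id),
                 indicator_id = as.character(df$indicator_id),
                 round = as.integer(df$round),
                 rating = as.integer(df$rating))
}

#' Load an expert-panel CSV
#'
#' Required columns: `expert_id` plus the four competency sub-scores
#' (`background`, `knowhow`, `anchored_behavior`, `engagement`); any extra
#' columns are kept as metadata.
#'
#' @param path CSV path.
#' @return tibble of expert profiles.
#' @export
load_panel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", names(COMPETENCY_CAPS))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("panel CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$expert_id <- as.character(df$expert_id)
  tibble::as_tibble(df)
}

report_numbers <- function(results) {
  # flatten the numeric fields of a stage result at report rounding
  out <- list()
  if (!is.null(results$qi)) out$qi <- round_half_up(results$qi, 2)
  if (!is.null(results$layer_scores)) {
    out$layer_scores <- as.list(round_half_up(results$layer_scores, 2))
  }
  if (!is.null(results$consensus)) {
    cs <- results$consensus
    out$consensus <- list(w = round_half_up(cs$w, 3),
                          chi2 = round_half_up(cs$chi2, 3),
                          df = cs$df, p = signif(cs$p, 3))
  }
  if (!is.null(results$alpha)) out$alpha <- round_half_up(results$alpha, 3)
  if (!is.null(results$fit)) {
    fi <- results$fit
    out$fit <- list(cmin = round_half_up(fi$cmin, 3), df = fi$df,
                    cmin_df = round_half_up(fi$cmin_df, 3),
                    srmr = round_half_up(fi$srmr, 3),
                    cmin_df_class = fi$cmin_df_class,
                    srmr_acceptable = fi$srmr_acceptable)
  }
  if (!is.null(results$weights)) {
    out$weights <- as.list(round_half_up(results$weights, 3))
  }
  out
}

#' Render a stage report
#'
#' Produces a JSON or markdown document from a list of stage results
#' (recognised fields: `qi`, `layer_scores`, `consensus`, `alpha`, `fit`,
#' `weights`), with scores at 2 decimals and weights/fit indices at 3, plus a
#' provenance block (seed and config snapshot) sufficient to reproduce the
#' run. The two formats agree on every numeric field.
#'
#' @param results named list of stage results.
#' @param format "json" or "markdown".
#' @param provenance named list recorded verbatim (seeds, config, inputs).
#' @return a single character string (the document).
#' @export
render_report <- function(results, format = c("json", "markdown"),
                          provenance = list()) {
  format <- match.arg(format)
  nums <- report_numbers(results)
  if (format == "json") {
    return(jsonlite::toJSON(list(results = nums, provenance = provenance),
                            auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }
  lines <- c("# Evaluation report", "")
  fmt_kv <- function(name, val) {
    if (is.list(val)) {
      c(sprintf("## %s", name), "",
        unlist(lapply(names(val), function(k) {
          v <- val[[k]]
          sprintf("- %s: %s", k, paste(format(v, scientific = FALSE),
                                       collapse = ", "))
        })), "")
    } else {
      sprintf("- %s: %s", name, format(val, scientific = FALSE))
    }
  }
  for (nm in names(nums)) lines <- c(lines, fmt_kv(nm, nums[[nm]]))
  if (length(provenance) > 0) {
    lines <- c(lines, "## Provenance", "",
               vapply(names(provenance), function(k) {
                 sprintf("- %s: %s",
                         k, paste(format(provenance[[k]]), collapse = " "))
               }, character(1)), "")
  }
  paste(lines, collapse = "\n")
}
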