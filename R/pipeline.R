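## ---- end-to-end classification pipeline -------------------------------------

#' Classify variants end to end
#'
#' Runs the full pipeline on an aligned homolog family: redundancy removal,
#' gappy-column filtering, per-variant region selection, subfamily
#' clustering, per-cluster profile HMM scoring, and logistic soft
#' classification. Stage errors are reported per variant (with the stage
#' name) rather than aborting the run; no-call variants are reported, not
#' dropped.
#'
#' @param msa an [aa_msa()] with the query (wild-type) row designated.
#' @param variants character vector of `"A95E"`-style variants, or a list of
#'   [parse_variant()] objects.
#' @param cutoff score cutoff t (default 2.7).
#' @param clustering `"ceo"` or `"kmeans"`.
#' @param k cluster count for K-means (ignored by CEO, which chooses k).
#' @param restarts clustering restarts (default 2 for CEO, 100 for K-means).
#' @param shuffles Monte-Carlo permutations for the CEO expected entropy.
#' @param score_mode `"difference"` or `"ratio"`, see [hmmvar_score()].
#' @param identity_threshold redundancy threshold (default 0.95).
#' @param max_gap_fraction column gap-fraction threshold (default 0.99).
#' @param min_width minimum region width in columns (default 10).
#' @param extension_gap_fraction secondary-extension gap bound (default 0.10).
#' @param significance_floor bit-score floor for no-calls (default 0).
#' @param min_donor_size minimum non-target cluster size entering the
#'   minimum score; `NULL` (default) derives it from the cutoff in
#'   difference mode (`floor(pseudocount * (2^cutoff - 1)) + 1`, the
#'   smallest cluster whose profile can reach a score above the cutoff)
#'   and uses 2 in ratio mode.
#' @param pseudocount,match_gap_threshold profile construction parameters.
#' @param seed RNG seed used by the clustering stage.
#' @param out_dir optional output directory; when given, writes
#'   `results.tsv` (confidences rounded to 3 decimals) and `manifest.json`
#'   (configuration, seed, and per-stage row/column accounting).
#' @return data frame with one row per variant: variant, S0, Sx,
#'   argmin_cluster, k, L, A, the four confidences, predicted, no_call,
#'   stage/message for failed variants. Full precision is retained in the
#'   returned object.
#' @export
classify_variants <- function(msa, variants, cutoff = 2.7,
                              clustering = c("ceo", "kmeans"), k = 4L,
                              restarts = NULL, shuffles = 20L,
                              score_mode = c("difference", "ratio"),
                              identity_threshold = 0.95,
                              max_gap_fraction = 0.99,
                              min_width = 10L,
                              extension_gap_fraction = 0.10,
                              significance_floor = 0,
                              min_donor_size = NULL,
                              pseudocount = 1, match_gap_threshold = 0.5,
                              seed = 1L, out_dir = NULL) {
  clustering <- match.arg(clustering)
  score_mode <- match.arg(score_mode)
  if (is.null(restarts)) restarts <- if (clustering == "ceo") 2L else 100L
  if (is.null(min_donor_size)) {
    min_donor_size <- if (score_mode == "difference") {
      max(2L, as.integer(floor(pseudocount * (2^cutoff - 1))) + 1L)
    } else 2L
  }
  if (is.character(variants)) variants <- lapply(variants, parse_variant)

  n_rows_in <- nrow(msa$mat)
  dedup <- remove_redundant(msa, identity_threshold)
  filt <- filter_columns(dedup, max_gap_fraction)
  manifest_stages <- list(
    redundancy = list(rows_in = n_rows_in, rows_out = nrow(dedup$mat),
                      removed = n_rows_in - nrow(dedup$mat)),
    column_filter = list(columns_in = ncol(dedup$mat),
                         columns_out = ncol(filt$msa$mat),
                         removed = ncol(dedup$mat) - ncol(filt$msa$mat)))

  empty_row <- function(v) {
    data.frame(variant = format(v), S0 = NA_real_, Sx = NA_real_,
               argmin_cluster = NA_character_, k = NA_integer_,
               L = NA_real_, A = NA_real_,
               conf_LoF = NA_real_, conf_SoF = NA_real_,
               conf_GoF = NA_real_, conf_CoF = NA_real_,
               predicted = NA_character_, no_call = NA,
               stage = NA_character_, message = NA_character_,
               stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(structure(class = c("funmut_stage_error", "error", "condition"),
                     list(message = conditionMessage(e), call = NULL,
                          stage = stage)))
    })
  }

  variant_info <- list()
  rows <- lapply(variants, function(v) {
    out <- empty_row(v)
    res <- tryCatch({
      col0 <- run_stage("map_variant", map_variant_to_column(dedup, v))
      col <- filt$column_map[col0]
      if (is.na(col)) {
        run_stage("column_filter",
                  stop("variant column removed by quality filtering"))
      }
      window <- run_stage("select_region",
                          select_region(filt$msa, col, min_width,
                                        extension_gap_fraction))
      partition <- run_stage("clustering", {
        if (clustering == "ceo") {
          ceo_cluster(window, restarts = restarts, shuffles = shuffles,
                      seed = seed)
        } else {
          kmeans_cluster(window, k = k, restarts = restarts, seed = seed)
        }
      })
      scores <- run_stage("scoring",
                          score_variant_across_clusters(
                            window, partition, v,
                            significance_floor = significance_floor,
                            mode = score_mode, pseudocount = pseudocount,
                            match_gap_threshold = match_gap_threshold,
                            min_donor_size = min_donor_size))
      cls <- run_stage("classification", classify_variant(scores, cutoff))
      list(window = window, partition = partition, scores = scores, cls = cls)
    }, funmut_stage_error = function(e) e)

    if (inherits(res, "funmut_stage_error")) {
      out$stage <- res$stage
      out$message <- conditionMessage(res)
      return(out)
    }
    out$S0 <- res$scores$target_score
    out$Sx <- res$scores$min_other_score
    out$argmin_cluster <- res$scores$argmin_cluster
    out$k <- res$partition$k
    out$no_call <- res$cls$no_call
    out$predicted <- res$cls$predicted
    if (!res$cls$no_call) {
      out$L <- res$cls$loss_prob
      out$A <- res$cls$acquire_prob
      out[c("conf_LoF", "conf_SoF", "conf_GoF", "conf_CoF")] <-
        as.list(res$cls$confidence[c("LoF", "SoF", "GoF", "CoF")])
    }
    variant_info[[format(v)]] <<- list(
      window = c(res$window$first, res$window$last),
      window_rows = nrow(res$window$msa$mat),
      k = res$partition$k,
      cluster_sizes = res$partition$sizes)
    out
  })
  results <- do.call(rbind, rows)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    printed <- results
    num <- c("S0", "Sx", "L", "A", "conf_LoF", "conf_SoF", "conf_GoF", "conf_CoF")
    printed[num] <- lapply(printed[num], round, digits = 3)
    write.table(printed, file.path(out_dir, "results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("funmut")),
      seed = seed,
      config = list(cutoff = cutoff, clustering = clustering, k = k,
                    restarts = restarts, shuffles = shuffles,
                    score_mode = score_mode,
                    identity_threshold = identity_threshold,
                    max_gap_fraction = max_gap_fraction,
                    min_width = min_width,
                    extension_gap_fraction = extension_gap_fraction,
                    significance_floor = significance_floor,
                    min_donor_size = min_donor_size,
                    pseudocount = pseudocount,
                    match_gap_threshold = match_gap_threshold),
      stages = manifest_stages,
      variants = variant_info)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  results
}

#' Evaluate pipeline results against annotations
#'
#' Joins a result table from [classify_variants()] with a two-column
#' annotation table (variant, `"GoF"`/`"LoF"` label), builds the confusion
#' matrix over the annotated variants with usable predictions, and computes
#' the restricted binary metrics.
#'
#' @param results data frame from [classify_variants()].
#' @param annotations data frame with columns `variant` and `label`.
#' @return list with `confusion`, `metrics`, `n_annotated`, `n_predicted`.
#' @export
evaluate_predictions <- function(results, annotations) {
  stopifnot(all(c("variant", "label") %in% names(annotations)))
  merged <- merge(results, annotations, by = "variant")
  usable <- !is.na(merged$predicted) & merged$predicted %in% PRED_LEVELS
  conf <- confusion_matrix(merged$label[usable], merged$predicted[usable])
  list(confusion = conf, metrics = binary_metrics(conf),
       n_annotated = nrow(merged), n_predicted = sum(usable))
}
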