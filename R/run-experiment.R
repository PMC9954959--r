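#' Run a full CAD experiment
#'
#' Wires the whole pipeline on one table: simulate (or load), train each
#' requested trainer under each splitting scheme, aggregate the metric rows
#' per trainer, rank the sonographic signs with the unpruned Gini tree, grow
#' the prepruned guideline tree, and write every artifact to `out_dir`:
#'
#' * `metrics.tsv` — one row per scheme x trainer with AC/SN/SP (the layout
#'   of the per-experiment report tables),
#' * `aggregate.tsv` — the per-trainer means,
#' * `ranking.tsv` — the sign importance ranking,
#' * `guideline.txt` / `guideline.dot` — the prepruned guideline tree as an
#'   indented flowchart and as a Graphviz document,
#' * `manifest.json` — seeds, configuration echo and package version, enough
#'   to reproduce the run.
#'
#' Every stochastic stage receives a seed derived deterministically from
#' `seed`, so two runs with the same configuration produce byte-identical
#' reports.
#'
#' @param table optional `NoduleTable`; when `NULL` one is generated from
#'   `n_total`/`n_malignant`/`risk_lift`.
#' @param trainers character subset of `c("ga", "bp", "hybrid")`.
#' @param schemes character subset of the [split_plan()] schemes.
#' @param n_total,n_malignant,risk_lift generator settings used when `table`
#'   is `NULL`.
#' @param n_rules fuzzy rules per ANFIS model.
#' @param ga,bp trainer configurations (defaults: the study settings).
#' @param max_splits prepruning budget of the guideline tree.
#' @param signs sign columns to model (default all 27).
#' @param seed global seed.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, a list with the metrics data frame, aggregate rows,
#'   ranking, tree and manifest.
#' @export
run_experiment <- function(table = NULL,
                           trainers = c("ga", "bp", "hybrid"),
                           schemes = c("holdout_70_30", "holdout_80_20",
                                       "kfold_5", "kfold_10"),
                           n_total = 398, n_malignant = 284, risk_lift = 0.8,
                           n_rules = 10, ga = ga_config(), bp = bp_config(),
                           max_splits = 7, signs = paste0("P", 1:27),
                           seed = 1, out_dir = "anfiscad-run") {
  trainers <- match.arg(trainers, c("ga", "bp", "hybrid"),
                        several.ok = TRUE)
  if (is.null(table))
    table <- generate_nodules(n_total = n_total, n_malignant = n_malignant,
                              risk_lift = risk_lift, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list()
  for (tr in trainers) {
    for (sc in schemes) {
      # sub-seed derived from the global seed, stable across runs
      sub <- (seed * 131 + match(tr, c("ga", "bp", "hybrid")) * 17 +
                match(sc, schemes)) %% .Machine$integer.max
      cfg <- if (tr == "ga") {
        g <- ga; g$seed <- sub; g
      } else bp
      m <- evaluate_trainer(table, split_plan(sc, seed = sub),
                            trainer = tr, config = cfg, n_rules = n_rules,
                            signs = signs, seed = sub)
      rows[[length(rows) + 1]] <- data.frame(
        trainer = tr, scheme = sc,
        AC = round_half_up(m$accuracy), SN = round_half_up(m$sensitivity),
        SP = round_half_up(m$specificity))
    }
  }
  metrics <- do.call(rbind, rows)

  agg <- do.call(rbind, lapply(trainers, function(tr) {
    sub <- metrics[metrics$trainer == tr, ]
    a <- aggregate_mean(data.frame(accuracy = sub$AC, sensitivity = sub$SN,
                                   specificity = sub$SP))
    data.frame(trainer = tr, AC = a$accuracy, SN = a$sensitivity,
               SP = a$specificity)
  }))

  ranking <- rank_signs(table[signs], table$label)
  tree <- grow_tree(table[signs], table$label, max_splits = max_splits)

  utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(agg, file.path(out_dir, "aggregate.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ranking, file.path(out_dir, "ranking.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(guideline_text(tree), file.path(out_dir, "guideline.txt"))
  writeLines(guideline_dot(tree), file.path(out_dir, "guideline.dot"))

  manifest <- list(
    package = "anfiscad",
    version = as.character(utils::packageVersion("anfiscad")),
    seed = seed, trainers = trainers, schemes = schemes,
    n_total = nrow(table), n_rules = n_rules, risk_lift = risk_lift,
    max_splits = max_splits, signs = signs,
    ga = unclass(ga), bp = unclass(bp))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(metrics = metrics, aggregate = agg, ranking = ranking,
                 tree = tree, manifest = manifest))
}
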