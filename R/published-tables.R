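# Bundled reference rank tables: published top-10 pipeline rankings from
# three weak-signal benchmark datasets (rat tungsten inhalation, 3x8 design;
# zebrafish chronic irradiation; mouse MK-801 exposure, 3 vs 6 design).
# They serve as worked inputs for the aggregation stages and as external
# reference rankings for concordance reports.

#' Bundled published rank tables
#'
#' Top-10 pipeline rank tables from three published weak-signal RNA-Seq
#' benchmark datasets, shipped as plain TSV. `"rat_pa"` is a
#' precision/accuracy-mode table (columns `Precision`, `Accuracy`, `Sum`,
#' `Rank`, where `Precision`/`Accuracy` are component ranks, fractional
#' mid-ranks included); the `"*_clf"` tables are classifier-mode (columns
#' `Rank F1`, `Rank NMI`, `Sum`, `Rank DGE`, `Rank`).
#'
#' @param name one of `"rat_pa"`, `"rat_clf"`, `"zebrafish_clf"`,
#'   `"mice_clf"`.
#' @return data.frame as from [read_rank_table()].
#' @examples
#' t4 <- published_rank_table("mice_clf")
#' # re-derive the printed final ranks from the component ranks alone:
#' agg <- aggregate_classifier_ranks(final_ranks(t4) |> names(),
#'                                   t4[["Rank F1"]], t4[["Rank NMI"]],
#'                                   t4[["Rank DGE"]])
#' all(agg$Rank == t4$Rank[match(agg$Pipeline, names(final_ranks(t4)))])
#' @export
published_rank_table <- function(name = c("rat_pa", "rat_clf",
                                          "zebrafish_clf", "mice_clf")) {
  name <- match.arg(name)
  file <- c(rat_pa = "rat_precision_accuracy_top10.tsv",
            rat_clf = "rat_classifier_top10.tsv",
            zebrafish_clf = "zebrafish_classifier_top10.tsv",
            mice_clf = "mice_classifier_top10.tsv")[[name]]
  path <- system.file("extdata", file, package = "piperank", mustWork = TRUE)
  read_rank_table(path)
}
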