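# The constrained combinatorial space of candidate pipelines: every pipeline
# is one choice of trimmer x aligner x counting method x normalization, with
# compatibility restricted between counting and normalization only (e.g. TPM
# needs transcript-level quantification, TMM/RLE need raw counts).

#' Stage inventory of a pipeline space
#'
#' @param trimming,mapping,counting,normalization character vectors of tool /
#'   method identifiers, one per stage; non-empty, unique within a stage.
#' @return object of class `"stage_inventory"`.
#' @export
stage_inventory <- function(trimming, mapping, counting, normalization) {
  stages <- list(trimming = trimming, mapping = mapping,
                 counting = counting, normalization = normalization)
  for (nm in names(stages)) {
    s <- as.character(stages[[nm]])
    if (length(s) == 0L) pr_stop(sprintf("stage '%s' must have >= 1 tool", nm))
    if (anyDuplicated(s)) pr_stop(sprintf("duplicate ids in stage '%s'", nm))
    stages[[nm]] <- s
  }
  structure(stages, class = "stage_inventory")
}

#' @export
print.stage_inventory <- function(x, ...) {
  cat("stage_inventory:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

#' Counting/normalization compatibility table
#'
#' @param counting,normalization equal-length character vectors; row i states
#'   that `normalization[i]` may follow `counting[i]`.
#' @return object of class `"compatibility_table"` (a data.frame).
#' @export
compatibility_table <- function(counting, normalization) {
  df <- data.frame(counting = as.character(counting),
                   normalization = as.character(normalization),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) pr_stop("compatibility table must have >= 1 pair")
  if (anyDuplicated(df)) pr_stop("duplicate counting/normalization pairs")
  class(df) <- c("compatibility_table", "data.frame")
  df
}

#' Default pipeline space
#'
#' The bundled stage inventory (3 trimmers, 3 aligners, 4 counting methods, 6
#' normalization methods) and counting/normalization compatibility table (10
#' allowed pairs), giving 3 x 3 x 10 = 90 pipelines. The compatibility table
#' is a reconstruction: transcript-assembly quantifiers pair with
#' length-aware normalizations (StringTie with TPM/FPKM/coverage, Cufflinks
#' with FPKM), union/intersection read counters with count-scaling factors
#' (TMM, RLE, upper quartile). Override via [compatibility_table()] or a
#' pipeline-space config file when your tool chain differs.
#'
#' @return `default_stage_inventory()`: a [stage_inventory()];
#'   `default_compatibility()`: a [compatibility_table()].
#' @export
default_stage_inventory <- function() {
  stage_inventory(
    trimming      = c("Bbduk", "Cutadapt", "Trimmomatic"),
    mapping       = c("TopHat2", "STAR", "HiSat2"),
    counting      = c("StringTie", "Cufflinks", "HTSeq_U", "HTSeq_IN"),
    normalization = c("TPM", "FPKM", "Coverage", "TMM", "RLE", "UQ")
  )
}

#' @rdname default_stage_inventory
#' @export
default_compatibility <- function() {
  compatibility_table(
    counting = c("StringTie", "StringTie", "StringTie", "Cufflinks",
                 "HTSeq_U", "HTSeq_U", "HTSeq_U",
                 "HTSeq_IN", "HTSeq_IN", "HTSeq_IN"),
    normalization = c("TPM", "FPKM", "Coverage", "FPKM",
                      "TMM", "RLE", "UQ",
                      "TMM", "RLE", "UQ")
  )
}

#' Enumerate the pipeline space
#'
#' Full cross product trimming x mapping x allowed (counting, normalization)
#' pairs, in deterministic lexicographic order of the four stage ids (C
#' locale), with a canonical label `trim+map+count+norm` per pipeline.
#'
#' @param inventory a [stage_inventory()]; default [default_stage_inventory()].
#' @param compat a [compatibility_table()], or `"all"` to allow every
#'   counting/normalization pair; default [default_compatibility()].
#' @return data.frame with columns `trimming`, `mapping`, `counting`,
#'   `normalization`, `label`, one row per pipeline.
#' @examples
#' nrow(enumerate_pipelines())            # 90
#' nrow(enumerate_pipelines(compat = "all"))  # 216
#' @export
enumerate_pipelines <- function(inventory = default_stage_inventory(),
                                compat = default_compatibility()) {
  if (identical(compat, "all")) {
    compat <- compatibility_table(
      counting = rep(inventory$counting, each = length(inventory$normalization)),
      normalization = rep(inventory$normalization, length(inventory$counting))
    )
  }
  unknown_c <- setdiff(compat$counting, inventory$counting)
  unknown_n <- setdiff(compat$normalization, inventory$normalization)
  if (length(unknown_c) || length(unknown_n)) {
    pr_stop(sprintf("compatibility table references unknown ids: %s",
                    paste(c(unknown_c, unknown_n), collapse = ", ")))
  }
  uncovered <- setdiff(inventory$counting, compat$counting)
  if (length(uncovered)) {
    pr_stop(sprintf("counting tool(s) with no allowed normalization: %s",
                    paste(uncovered, collapse = ", ")))
  }
  grid <- expand.grid(pair = seq_len(nrow(compat)),
                      mapping = inventory$mapping,
                      trimming = inventory$trimming,
                      stringsAsFactors = FALSE)
  df <- data.frame(trimming = grid$trimming,
                   mapping = grid$mapping,
                   counting = compat$counting[grid$pair],
                   normalization = compat$normalization[grid$pair],
                   stringsAsFactors = FALSE)
  o <- order(df$trimming, df$mapping, df$counting, df$normalization,
             method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df$label <- pipeline_label(df)
  if (anyDuplicated(df$label)) pr_stop("duplicate pipelines after enumeration")
  df
}

#' Canonical pipeline labels
#'
#' @param spec data.frame with `trimming`, `mapping`, `counting`,
#'   `normalization` columns.
#' @return character vector `trim+map+count+norm`.
#' @export
pipeline_label <- function(spec) {
  paste(spec$trimming, spec$mapping, spec$counting, spec$normalization,
        sep = "+")
}

#' Parse a canonical pipeline label
#'
#' Inverse of [pipeline_label()]: `parse_pipeline_label(pipeline_label(s))`
#' reproduces `s`.
#'
#' @param label string in `trim+map+count+norm` form.
#' @param inventory optional [stage_inventory()]; when given, each stage id
#'   is checked against it.
#' @return one-row data.frame with the four stage columns and `label`.
#' @export
parse_pipeline_label <- function(label, inventory = NULL) {
  parts <- strsplit(label, "+", fixed = TRUE)[[1L]]
  if (length(parts) != 4L) {
    pr_stop(sprintf("pipeline label '%s' must have 4 '+'-separated stages, got %d",
                    label, length(parts)))
  }
  spec <- data.frame(trimming = parts[1L], mapping = parts[2L],
                     counting = parts[3L], normalization = parts[4L],
                     stringsAsFactors = FALSE)
  if (!is.null(inventory)) {
    for (nm in names(spec)) {
      if (!spec[[nm]] %in% inventory[[nm]]) {
        pr_stop(sprintf("unknown %s id '%s' in label '%s'", nm, spec[[nm]], label))
      }
    }
  }
  spec$label <- pipeline_label(spec)
  spec
}

#' Read / write a pipeline-space configuration
#'
#' YAML schema: `schema_version`, `inventory` (four named id lists) and
#' `allowed_pairs` (list of two-element `[counting, normalization]` pairs).
#'
#' @param path YAML file path.
#' @return list with `inventory` ([stage_inventory()]) and `compat`
#'   ([compatibility_table()]).
#' @export
read_pipeline_space <- function(path) {
  cfg <- yaml::read_yaml(path)
  inv <- cfg$inventory
  if (is.null(inv)) pr_stop(sprintf("no 'inventory' in pipeline-space config '%s'", path))
  inventory <- stage_inventory(inv$trimming, inv$mapping, inv$counting,
                               inv$normalization)
  pairs <- cfg$allowed_pairs
  if (is.null(pairs)) pr_stop(sprintf("no 'allowed_pairs' in '%s'", path))
  compat <- compatibility_table(
    counting = vapply(pairs, function(p) as.character(p[[1L]]), character(1)),
    normalization = vapply(pairs, function(p) as.character(p[[2L]]), character(1))
  )
  list(inventory = inventory, compat = compat)
}

#' @rdname read_pipeline_space
#' @param inventory a [stage_inventory()].
#' @param compat a [compatibility_table()].
#' @export
write_pipeline_space <- function(inventory, compat, path) {
  cfg <- list(
    schema_version = 1L,
    inventory = lapply(unclass(inventory), as.list),
    allowed_pairs = lapply(seq_len(nrow(compat)), function(i) {
      list(compat$counting[i], compat$normalization[i])
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
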