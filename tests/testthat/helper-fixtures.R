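# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

em <- function(values, lengths = NULL, libsizes = NULL, unit = "raw_count") {
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, gene_lengths = lengths, library_sizes = libsizes,
                    unit_tag = unit)
}

rand_counts <- function(ng, ns, lambda = 100, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(ng * ns, lambda), ng, ns,
              dimnames = list(sprintf("g%d", seq_len(ng)),
                              sprintf("s%d", seq_len(ns))))
  m
}

# matrix whose log2(x + 1) equals `y` exactly (y >= 0)
from_log2 <- function(y) 2^y - 1

meta_df <- function(groups) {
  validate_metadata(data.frame(
    sample_id = unlist(lapply(names(groups), function(g)
      sprintf("%s_%02d", g, seq_len(groups[[g]])))),
    group_label = rep(names(groups), unlist(groups)),
    stringsAsFactors = FALSE))
}
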