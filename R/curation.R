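# Repertoire curation: quality control, identity-based deduplication and
# train/validation/test partitioning. The contract of this module is the
# leakage guarantee: deduplication at a 95% identity threshold is performed
# BEFORE splitting, so no test-set sequence has >= 95% identity to any
# training-set sequence.

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear gap
#' penalty -1; ties are broken toward alignments with fewer gaps. Identity is
#' the number of exact matches divided by the alignment length. Symmetric in
#' its arguments.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return Identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  assert_that(is.character(a) && is.character(b) &&
              length(a) == 1 && length(b) == 1, "a and b must be single strings")
  assert_that(nchar(a) > 0 && nchar(b) > 0, "sequences must be non-empty")
  .nw_identity_cpp(a, b)
}

#' Quality-control filter
#'
#' Retains records that (i) have a CDR3, (ii) carry complete V(D)J annotation
#' for their chain (V+D+J for heavy, V+J for light), and (iii) have a CDR3
#' between 6 and 29 amino acids long. Rules are applied in that precedence
#' order, so each rejected record is counted under exactly one rule.
#'
#' @param records data.frame of BCR records.
#' @param cdr3_bounds Length window, default `c(6, 29)`; applied to light
#'   chains too (single code path).
#' @return list with `kept` (data.frame) and `report` (named integer vector
#'   of per-rule rejection counts: missing_cdr3, incomplete_vdj,
#'   cdr3_length).
#' @export
qc_filter <- function(records, cdr3_bounds = c(6L, 29L)) {
  n <- nrow(records)
  miss_cdr3 <- is.na(records$hcdr3) | nchar(records$hcdr3) == 0
  incomplete <- !miss_cdr3 &
    (is.na(records$v_call) | is.na(records$j_call) |
       (records$chain == "heavy" & is.na(records$d_call)))
  len <- nchar(records$hcdr3)
  bad_len <- !miss_cdr3 & !incomplete &
    (len < cdr3_bounds[1] | len > cdr3_bounds[2])
  keep <- !(miss_cdr3 | incomplete | bad_len)
  report <- c(missing_cdr3 = sum(miss_cdr3),
              incomplete_vdj = sum(incomplete),
              cdr3_length = sum(bad_len))
  stopifnot(sum(keep) + sum(report) == n)
  list(kept = records[keep, , drop = FALSE], report = report)
}

#' Greedy identity-clustering deduplication
#'
#' CD-HIT-style greedy incremental clustering: records are sorted by
#' descending sequence length; each record joins the first existing cluster
#' whose representative has identity >= `threshold` to it, otherwise it
#' founds a new cluster. Exactly one representative (the founder, the longest
#' member) is retained per cluster. Heavy and light chains are clustered
#' separately.
#'
#' @param records data.frame of BCR records.
#' @param threshold Identity threshold in (0, 1\], default 0.95.
#' @return list with `representatives` (data.frame) and `cluster_map`
#'   (data.frame: sequence_id, cluster_id, representative_id,
#'   identity_to_rep).
#' @export
dedup_cluster <- function(records, threshold = 0.95) {
  assert_that(threshold > 0 && threshold <= 1, "threshold must lie in (0, 1]")
  per_chain <- function(df, tag) {
    if (nrow(df) == 0) {
      return(list(rep_idx = integer(0),
                  map = data.frame(sequence_id = character(0),
                                   cluster_id = character(0),
                                   representative_id = character(0),
                                   identity_to_rep = numeric(0))))
    }
    ord <- order(-nchar(df$sequence))
    reps <- integer(0)             # indices into df (in ord processing order)
    assign_cluster <- integer(nrow(df))
    ident <- numeric(nrow(df))
    for (i in ord) {
      hit <- if (length(reps) == 0) 0L else
        .nw_first_hit_cpp(df$sequence[i], df$sequence[reps], threshold)
      if (hit == 0L) {
        reps <- c(reps, i)
        assign_cluster[i] <- length(reps)
        ident[i] <- 1.0
      } else {
        assign_cluster[i] <- hit
        ident[i] <- .nw_identity_cpp(df$sequence[i], df$sequence[reps[hit]])
      }
    }
    map <- data.frame(
      sequence_id = df$id,
      cluster_id = sprintf("%s_cluster_%05d", tag, assign_cluster),
      representative_id = df$id[reps[assign_cluster]],
      identity_to_rep = ident,
      stringsAsFactors = FALSE
    )
    list(rep_idx = reps, map = map)
  }
  heavy <- per_chain(records[records$chain == "heavy", , drop = FALSE], "H")
  light <- per_chain(records[records$chain != "heavy", , drop = FALSE], "L")
  rep_ids <- c(records$id[records$chain == "heavy"][heavy$rep_idx],
               records$id[records$chain != "heavy"][light$rep_idx])
  list(representatives = records[records$id %in% rep_ids, , drop = FALSE],
       cluster_map = rbind(heavy$map, light$map))
}

#' Partition records into train/validation/test
#'
#' Uniform random shuffle by `seed`, then contiguous assignment by cumulative
#' ratio with floor-then-distribute rounding: remaining records go first to
#' partitions left empty by the floor (so no configured partition is starved
#' on tiny inputs), then to the largest fractional parts, ties in ratio
#' order. Records are expected to be deduplicated already (pipeline
#' ordering; not checked here).
#'
#' @param records data.frame.
#' @param ratios Three positive weights, default `c(90, 5, 5)`.
#' @param seed Integer seed.
#' @return list with `train`, `validation`, `test` (data.frames), `ratios`,
#'   `seed`.
#' @export
split_records <- function(records, ratios = c(90, 5, 5), seed = 1L) {
  assert_that(length(ratios) == 3 && all(ratios > 0), "ratios must be 3 positive numbers")
  n <- nrow(records)
  set.seed(seed)
  ord <- sample.int(n)
  frac <- ratios / sum(ratios)
  counts <- floor(n * frac)
  rem <- n - sum(counts)
  if (rem > 0) {
    fpart <- n * frac - counts
    extra <- order(counts > 0, -fpart, seq_along(frac))[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  bounds <- cumsum(counts)
  idx <- list(train = ord[seq_len(counts[1])],
              validation = if (counts[2] > 0) ord[(bounds[1] + 1):bounds[2]] else integer(0),
              test = if (counts[3] > 0) ord[(bounds[2] + 1):bounds[3]] else integer(0))
  list(train = records[idx$train, , drop = FALSE],
       validation = records[idx$validation, , drop = FALSE],
       test = records[idx$test, , drop = FALSE],
       ratios = ratios, seed = seed)
}

#' Maximum cross-set identity
#'
#' Audit statistic for the leakage guarantee: the maximum pairwise identity
#' between any test-set and any training-set sequence, optionally over a
#' random subsample of the cross product.
#'
#' @param test_set,train_set data.frames of records.
#' @param sample_n Optional count: subsample each set to at most this many
#'   records (seeded by `seed`) before the exhaustive cross product.
#' @param seed Seed for subsampling.
#' @return Maximum identity fraction.
#' @export
max_cross_identity <- function(test_set, train_set, sample_n = NULL, seed = 1L) {
  assert_that(nrow(test_set) > 0 && nrow(train_set) > 0,
              "both sets must be non-empty")
  xs <- test_set$sequence
  ys <- train_set$sequence
  if (!is.null(sample_n)) {
    set.seed(seed)
    if (length(xs) > sample_n) xs <- sample(xs, sample_n)
    if (length(ys) > sample_n) ys <- sample(ys, sample_n)
  }
  .nw_max_cross_cpp(xs, ys)
}

#' Curate a repertoire end to end
#'
#' QC filter, then per-chain greedy deduplication at `threshold`, then a
#' seeded 90:5:5 (by default) split. Returns all intermediate artifacts.
#'
#' @param records data.frame of BCR records.
#' @param threshold Dedup identity threshold.
#' @param ratios Split ratios.
#' @param seed Split seed.
#' @return list: `qc_report`, `cluster_map`, `split` (list train/validation/
#'   test), `n_input`, `n_kept`, `n_representatives`.
#' @export
curate <- function(records, threshold = 0.95, ratios = c(90, 5, 5), seed = 1L) {
  qc <- qc_filter(records)
  dd <- dedup_cluster(qc$kept, threshold = threshold)
  sp <- split_records(dd$representatives, ratios = ratios, seed = seed)
  list(qc_report = qc$report, cluster_map = dd$cluster_map, split = sp,
       n_input = nrow(records), n_kept = nrow(qc$kept),
       n_representatives = nrow(dd$representatives))
}
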