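# Synthetic BCR repertoire simulator: germline V(D)J recombination with
# junctional diversity, subtype-dependent somatic hypermutation (SHM) and
# isotype usage, and planted subtype-specific HCDR3 motifs. The simulator is
# the test bed for every downstream stage: it produces repertoires with the
# statistical structure the model assumes (labelled subtypes, mutation
# gradients, learnable sequence signal) without any external download.

#' Build random germline segment pools
#'
#' Generates amino-acid germline segments for heavy-chain V, D and J genes and
#' light-chain V and J genes, each with a unique gene symbol. The default
#' configuration yields 55 + 27 + 6 + 120 + 22 = 230 distinct gene symbols so
#' that the composite vocabulary built from these pools plus the five isotype
#' labels and five special tokens totals 260 tokens.
#'
#' V segments end with the conserved cysteine anchor that opens the CDR3;
#' heavy J segments start with the conserved tryptophan (WGQ motif), light J
#' segments with the FG motif.
#'
#' @param n_v,n_d,n_j Heavy-chain V/D/J pool sizes.
#' @param n_light_v,n_light_j Light-chain V/J pool sizes (split between
#'   kappa and lambda symbols).
#' @param seed Integer seed; pools are deterministic per seed.
#' @return An object of class `germline_pools`: a list with elements
#'   `v_segments`, `d_segments`, `j_segments`, `light_v_segments`,
#'   `light_j_segments`, each a named character vector (names are gene
#'   symbols, values amino-acid strings).
#' @export
build_germline_pools <- function(n_v = 55L, n_d = 27L, n_j = 6L,
                                 n_light_v = 120L, n_light_j = 22L,
                                 seed = 1L) {
  counts <- c(n_v, n_d, n_j, n_light_v, n_light_j)
  assert_that(all(counts >= 1), "all pool sizes must be >= 1")
  set.seed(seed)
  seg <- function(sym, len_lo, len_hi, n, prefix = "", suffix = "") {
    lens <- sample_range(len_lo, len_hi, n)
    seqs <- vapply(lens, function(L) {
      core <- random_aa(max(L - nchar(prefix) - nchar(suffix), 1))
      paste0(prefix, core, suffix)
    }, character(1))
    names(seqs) <- sym
    seqs
  }
  v_sym <- sprintf("IGHV%d-%d", 1 + (seq_len(n_v) - 1) %% 7,
                   1 + (seq_len(n_v) - 1) %/% 7)
  d_sym <- sprintf("IGHD%d-%d", 1 + (seq_len(n_d) - 1) %% 7,
                   1 + (seq_len(n_d) - 1) %/% 7)
  j_sym <- sprintf("IGHJ%d", seq_len(n_j))
  n_k <- ceiling(n_light_v / 2)
  lv_sym <- c(sprintf("IGKV%d-%d", 1 + (seq_len(n_k) - 1) %% 7,
                      1 + (seq_len(n_k) - 1) %/% 7),
              sprintf("IGLV%d-%d", 1 + (seq_len(n_light_v - n_k) - 1) %% 7,
                      1 + (seq_len(n_light_v - n_k) - 1) %/% 7))
  n_kj <- ceiling(n_light_j / 2)
  lj_sym <- c(sprintf("IGKJ%d", seq_len(n_kj)),
              sprintf("IGLJ%d", seq_len(n_light_j - n_kj)))
  pools <- list(
    v_segments = seg(v_sym, 88, 96, n_v, suffix = "C"),
    d_segments = seg(d_sym, 3, 8, n_d),
    j_segments = seg(j_sym, 12, 16, n_j, prefix = "WG"),
    light_v_segments = seg(lv_sym, 80, 88, n_light_v, suffix = "C"),
    light_j_segments = seg(lj_sym, 9, 12, n_light_j, prefix = "FG")
  )
  structure(pools, class = "germline_pools")
}

#' Gene symbols of a germline pool set
#' @param pools A `germline_pools` object.
#' @return Character vector of all (unique) gene symbols.
#' @export
pool_gene_symbols <- function(pools) {
  unname(unlist(lapply(pools, names)))
}

# Deterministic subtype -> planted HCDR3 motif table. Distinct 5-mers chosen
# to be rare under the uniform background (p ~ 20^-5 per position).
SUBTYPE_MOTIF_TABLE <- c("WDYWG", "GSSGY", "RRDFT", "YYGMD", "PPHNK",
                         "KKLTE", "CQQWE", "MMFVA", "HHTRS", "LLNPD")

#' Subtype-specific planted motifs
#'
#' Maps an ordered set of subtype labels onto distinct 5-mer motifs that the
#' simulator plants in the HCDR3 (or light CDR3) of records of that subtype.
#' The mapping is deterministic in the label order.
#'
#' @param subtype_labels Character vector of labels (max 10).
#' @return Named character vector label -> motif.
#' @export
subtype_motifs <- function(subtype_labels) {
  assert_that(length(subtype_labels) <= length(SUBTYPE_MOTIF_TABLE),
              "at most 10 subtype labels supported")
  setNames(SUBTYPE_MOTIF_TABLE[seq_along(subtype_labels)], subtype_labels)
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the repertoire simulator. The
#' defaults emulate a natural human repertoire: six canonical B-cell subtypes
#' with naive cells predominating, an SHM gradient that increases from
#' immature (no mutation) to plasma cells, and isotype usage that shifts from
#' IgM/IgD dominance in antigen-inexperienced subtypes to IgG/IgA dominance
#' after class switching.
#'
#' @param n_records Number of records to simulate.
#' @param subtype_labels Ordered label set.
#' @param subtype_proportions Simplex weights over subtypes (sum to 1).
#' @param shm_rate_per_subtype Per-residue substitution probability in
#'   \[0, 0.25\], one per subtype.
#' @param isotype_distribution_per_subtype Matrix (subtypes x 5 isotypes,
#'   columns in `ISOTYPES` order IgA/IgD/IgE/IgG/IgM), rows on the simplex.
#' @param motif_strength Probability that the subtype's motif is planted in
#'   the CDR3 of a record.
#' @param fraction_heavy Probability a record is a heavy chain.
#' @param seed Integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_records = 2000L,
                       subtype_labels = c("immature", "naive",
                                          "unswitched_memory",
                                          "switched_memory",
                                          "plasmablast", "plasma"),
                       subtype_proportions = NULL,
                       shm_rate_per_subtype = NULL,
                       isotype_distribution_per_subtype = NULL,
                       motif_strength = 0.8,
                       fraction_heavy = 0.85,
                       seed = 1L) {
  k <- length(subtype_labels)
  if (is.null(subtype_proportions)) {
    subtype_proportions <- if (k == 6) {
      c(0.05, 0.45, 0.10, 0.20, 0.08, 0.12)
    } else rep(1 / k, k)
  }
  if (is.null(shm_rate_per_subtype)) {
    shm_rate_per_subtype <- if (k == 6) {
      c(0, 0.005, 0.02, 0.05, 0.06, 0.08)
    } else seq(0, 0.08, length.out = k)
  }
  if (is.null(isotype_distribution_per_subtype)) {
    # columns: IgA IgD IgE IgG IgM
    base <- rbind(
      c(0.00, 0.10, 0.00, 0.00, 0.90),  # immature
      c(0.00, 0.40, 0.00, 0.00, 0.60),  # naive
      c(0.00, 0.20, 0.00, 0.00, 0.80),  # unswitched memory
      c(0.30, 0.00, 0.02, 0.60, 0.08),  # switched memory
      c(0.25, 0.00, 0.05, 0.70, 0.00),  # plasmablast
      c(0.35, 0.00, 0.05, 0.60, 0.00)   # plasma
    )
    isotype_distribution_per_subtype <-
      base[rep_len(seq_len(nrow(base)), k), , drop = FALSE]
  }
  cfg <- list(n_records = as.integer(n_records),
              subtype_labels = subtype_labels,
              subtype_proportions = subtype_proportions,
              shm_rate_per_subtype = shm_rate_per_subtype,
              isotype_distribution_per_subtype = isotype_distribution_per_subtype,
              motif_strength = motif_strength,
              fraction_heavy = fraction_heavy,
              motifs = subtype_motifs(subtype_labels),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  assert_that(cfg$n_records >= 1, "n_records must be >= 1")
  k <- length(cfg$subtype_labels)
  assert_that(!anyDuplicated(cfg$subtype_labels), "subtype labels must be unique")
  assert_that(length(cfg$subtype_proportions) == k &&
              abs(sum(cfg$subtype_proportions) - 1) < 1e-9,
              "subtype_proportions must sum to 1")
  assert_that(all(cfg$subtype_proportions >= 0), "proportions must be >= 0")
  assert_that(length(cfg$shm_rate_per_subtype) == k &&
              all(cfg$shm_rate_per_subtype >= 0 & cfg$shm_rate_per_subtype <= 0.25),
              "shm rates must lie in [0, 0.25]")
  iso <- cfg$isotype_distribution_per_subtype
  assert_that(is.matrix(iso) && nrow(iso) == k && ncol(iso) == 5 &&
              all(abs(rowSums(iso) - 1) < 1e-9) && all(iso >= 0),
              "isotype distributions must be k x 5 rows on the simplex")
  assert_that(cfg$motif_strength >= 0 && cfg$motif_strength <= 1,
              "motif_strength must lie in [0, 1]")
  assert_that(cfg$fraction_heavy >= 0 && cfg$fraction_heavy <= 1,
              "fraction_heavy must lie in [0, 1]")
  invisible(cfg)
}

#' @noRd
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(list(sequence = seq, n_mutations = 0L))
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  n <- sum(hit)
  if (n > 0) {
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(AA_ALPHABET, chars[i]), 1)
    }
  }
  list(sequence = paste(chars, collapse = ""), n_mutations = as.integer(n))
}

#' Simulate one BCR record
#'
#' Assembles a germline V(+junction+D+junction)+J concatenation (heavy) or
#' V+junction+J (light), records the CDR3 span from the terminal V-segment
#' cysteine anchor up to the start of the J segment, applies point
#' substitutions at the subtype's SHM rate, draws an isotype from the
#' subtype's isotype distribution (heavy chains; light chains carry none),
#' and plants the subtype motif in the CDR3 with probability
#' `config$motif_strength`.
#'
#' @param pools `germline_pools`.
#' @param subtype One of `config$subtype_labels`.
#' @param config `sim_config`.
#' @param seed Optional seed for this record.
#' @param chain Force `"heavy"` or `"light"`; default draws from
#'   `config$fraction_heavy`.
#' @return One-row data.frame with columns id, chain, locus, sequence, hcdr3,
#'   hcdr3_start, hcdr3_end (0-based half-open), v_call, d_call, j_call,
#'   isotype, subtype, n_mutations.
#' @export
simulate_record <- function(pools, subtype, config, seed = NULL, chain = NULL) {
  si <- match(subtype, config$subtype_labels)
  if (is.na(si)) stop("unknown subtype: ", subtype, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(chain)) {
    chain <- if (runif(1) < config$fraction_heavy) "heavy" else "light"
  }
  if (chain == "heavy") {
    vi <- sample(length(pools$v_segments), 1)
    di <- sample(length(pools$d_segments), 1)
    ji <- sample(length(pools$j_segments), 1)
    v <- pools$v_segments[[vi]]; d <- pools$d_segments[[di]]
    j <- pools$j_segments[[ji]]
    jn1 <- random_aa(sample_range(0L, 6L)); jn2 <- random_aa(sample_range(0L, 6L))
    seq <- paste0(v, jn1, d, jn2, j)
    cdr3_start <- nchar(v) - 1L                     # the anchor cysteine
    cdr3_end <- nchar(v) + nchar(jn1) + nchar(d) + nchar(jn2)
    v_call <- names(pools$v_segments)[vi]
    d_call <- names(pools$d_segments)[di]
    j_call <- names(pools$j_segments)[ji]
    isotype <- sample(ISOTYPES, 1, prob = config$isotype_distribution_per_subtype[si, ])
    locus <- "IGH"
  } else {
    vi <- sample(length(pools$light_v_segments), 1)
    ji <- sample(length(pools$light_j_segments), 1)
    v <- pools$light_v_segments[[vi]]; j <- pools$light_j_segments[[ji]]
    jn1 <- random_aa(sample_range(5L, 10L))
    seq <- paste0(v, jn1, j)
    cdr3_start <- nchar(v) - 1L
    cdr3_end <- nchar(v) + nchar(jn1)
    v_call <- names(pools$light_v_segments)[vi]
    d_call <- NA_character_
    j_call <- names(pools$light_j_segments)[ji]
    isotype <- NA_character_
    locus <- if (startsWith(v_call, "IGK")) "IGK" else "IGL"
  }
  mut <- mutate_sequence(seq, config$shm_rate_per_subtype[si])
  seq <- mut$sequence
  # plant the subtype motif inside the CDR3 (after the anchor), overwriting
  # residues in place so sequence length and the span are unchanged
  if (runif(1) < config$motif_strength) {
    motif <- config$motifs[[subtype]]
    at <- cdr3_start + 2L                           # 1-based, after anchor C
    len <- min(nchar(motif), nchar(seq) - at + 1L)
    substr(seq, at, at + len - 1L) <- substr(motif, 1L, len)
  }
  hcdr3 <- substr(seq, cdr3_start + 1L, cdr3_end)
  data.frame(id = NA_character_, chain = chain, locus = locus,
             sequence = seq, hcdr3 = hcdr3,
             hcdr3_start = cdr3_start, hcdr3_end = cdr3_end,
             v_call = v_call, d_call = d_call, j_call = j_call,
             isotype = isotype, subtype = subtype,
             n_mutations = mut$n_mutations,
             stringsAsFactors = FALSE)
}

#' Simulate a labelled repertoire
#'
#' Draws subtype labels from the configured proportions and simulates one
#' record per draw. Deterministic per `config$seed`.
#'
#' @param config `sim_config`.
#' @param pools `germline_pools`.
#' @return data.frame of records (one row each, columns as
#'   [simulate_record()]).
#' @export
simulate_repertoire <- function(config, pools) {
  validate_sim_config(config)
  set.seed(config$seed)
  subtypes <- sample(config$subtype_labels, config$n_records, replace = TRUE,
                     prob = config$subtype_proportions)
  rows <- lapply(seq_len(config$n_records), function(i) {
    simulate_record(pools, subtypes[i], config)
  })
  out <- do.call(rbind, rows)
  out$id <- sprintf("seq_%06d", seq_len(nrow(out)))
  out
}

#' Simulate a paratope-labelled antibody set
#'
#' Generates `n` random amino-acid sequences, plants `motif` at a random
#' interior position of each, and emits per-residue binary contact labels
#' marking exactly the motif positions plus `n_random_contacts` additional
#' random positions. A synthetic stand-in for structure-derived paratope
#' annotations.
#'
#' @param n Number of records.
#' @param motif Amino-acid motif string (length >= 2).
#' @param seed Integer seed.
#' @param seq_length Sequence length range, `c(lo, hi)`.
#' @param n_random_contacts Extra random contact positions per record.
#' @param motif_start Optional fixed 0-based motif start (same for all
#'   records); default random per record.
#' @return data.frame with columns id, chain, sequence, labels (string of
#'   0/1, one per residue), motif_start, motif_end (0-based half-open).
#' @export
simulate_paratope_set <- function(n, motif = "YYGMD", seed = 1L,
                                  seq_length = c(100L, 130L),
                                  n_random_contacts = 4L,
                                  motif_start = NULL) {
  assert_that(n >= 1, "n must be >= 1")
  assert_that(nchar(motif) >= 2, "motif length must be >= 2")
  set.seed(seed)
  ml <- nchar(motif)
  rows <- lapply(seq_len(n), function(i) {
    L <- sample_range(seq_length[1], seq_length[2])
    if (ml > L) stop("motif longer than sequence", call. = FALSE)
    s <- random_aa(L)
    start <- if (is.null(motif_start)) sample_range(0L, L - ml) else motif_start
    if (start + ml > L) stop("motif does not fit at motif_start", call. = FALSE)
    substr(s, start + 1L, start + ml) <- motif
    lab <- integer(L)
    lab[(start + 1L):(start + ml)] <- 1L
    if (n_random_contacts > 0) {
      free <- setdiff(seq_len(L), (start + 1L):(start + ml))
      lab[sample(free, min(n_random_contacts, length(free)))] <- 1L
    }
    data.frame(id = sprintf("ab_%04d", i), chain = "heavy", sequence = s,
               labels = paste(lab, collapse = ""),
               motif_start = start, motif_end = start + ml,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
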