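# Composite tokenization: each record is encoded sentence-pair style as
#   [CLS] residues... [SEP] v (d) j isotype [SEP] [PAD]...
# merging the amino-acid sequence with its germline gene and isotype metadata.
# The vocabulary is partitioned into blocks: 5 special tokens, 20 amino
# acids, the gene symbols, and the isotype labels; at the reference
# configuration (230 gene symbols, 5 isotypes) it totals 260 tokens.
# Token ids are 0-based.

SPECIAL_TOKENS <- c("[CLS]", "[PAD]", "[MASK]", "[SEP]", "[UNK]")

#' Build the composite vocabulary
#'
#' Deterministic id assignment: special tokens 0-4 in the order \[CLS\],
#' \[PAD\], \[MASK\], \[SEP\], \[UNK\]; then the 20 amino acids
#' alphabetically; then gene symbols sorted; then isotype labels sorted.
#'
#' @param gene_symbols Duplicate-free character vector of gene symbols.
#' @param isotype_labels Duplicate-free character vector (default the five
#'   heavy-chain isotypes).
#' @return An object of class `bcr_vocab`: list with `tokens` (id i is
#'   `tokens[i + 1]`), `ids` (named integer vector token -> id), `blocks`
#'   (named list of 0-based id ranges), `size`.
#' @export
build_vocabulary <- function(gene_symbols, isotype_labels = ISOTYPES) {
  assert_that(!anyDuplicated(gene_symbols), "duplicate gene symbols")
  assert_that(!anyDuplicated(isotype_labels), "duplicate isotype labels")
  tokens <- c(SPECIAL_TOKENS, AA_ALPHABET, sort(gene_symbols),
              sort(isotype_labels))
  assert_that(!anyDuplicated(tokens), "token duplicated across blocks")
  n_g <- length(gene_symbols); n_i <- length(isotype_labels)
  blocks <- list(
    special = 0:4,
    amino_acid = 5:24,
    gene = if (n_g > 0) 25:(24 + n_g) else integer(0),
    isotype = if (n_i > 0) (25 + n_g):(24 + n_g + n_i) else integer(0)
  )
  structure(list(tokens = tokens,
                 ids = setNames(seq_along(tokens) - 1L, tokens),
                 blocks = blocks, size = length(tokens)),
            class = "bcr_vocab")
}

#' @export
print.bcr_vocab <- function(x, ...) {
  cat("<bcr_vocab>", x$size, "tokens:",
      paste(sprintf("%s=%d", names(x$blocks), lengths(x$blocks)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @noRd
vocab_id <- function(vocab, token) {
  id <- vocab$ids[token]
  ifelse(is.na(id) | is.na(token), vocab$ids[["[UNK]"]], id)
}

#' Encode one record
#'
#' Layout: `[CLS] residues... [SEP] v (d) j isotype [SEP]`, then `[PAD]` to
#' `max_len`. In `hcdr3` mode the residue segment is the HCDR3 only. The
#' metadata tail (V, D for heavy chains, J, isotype) is always preserved;
#' when the total exceeds `max_len` the residue segment is truncated from its
#' right (C-terminal) end. Unknown or absent metadata maps to `[UNK]`;
#' residues outside the 20-letter alphabet map to `[UNK]` with a warning.
#' The encoding is chain-agnostic: no token identifies the chain; light
#' chains simply omit the D slot.
#'
#' @param record One-row data.frame (or list) of BCR record fields.
#' @param vocab `bcr_vocab`.
#' @param mode `"full_length"` or `"hcdr3"`.
#' @param max_len Maximum encoded length (default 148).
#' @return An object of class `encoded_seq`: list with `ids` (0-based,
#'   length `max_len`), `pad_mask` (TRUE = real token), `category`
#'   (per-position `"special"`, `"residue"` or `"metadata"`), `source_id`.
#' @export
encode <- function(record, vocab, mode = c("full_length", "hcdr3"),
                   max_len = 148L) {
  mode <- match.arg(mode)
  seq_str <- if (mode == "hcdr3") record$hcdr3 else record$sequence
  assert_that(!is.na(seq_str) && nchar(seq_str) > 0,
              "record has no sequence for the requested mode")
  residues <- strsplit(seq_str, "")[[1]]
  unknown <- !(residues %in% AA_ALPHABET)
  if (any(unknown)) {
    warning(sum(unknown), " residue(s) outside the amino-acid alphabet; ",
            "substituting [UNK]")
    residues[unknown] <- "[UNK]"
  }
  meta_tokens <- c(record$v_call,
                   if (identical(record$chain, "heavy")) record$d_call,
                   record$j_call, record$isotype)
  meta_ids <- unname(vocab_id(vocab, as.character(meta_tokens)))
  n_meta <- length(meta_ids)
  budget <- max_len - 3L - n_meta          # [CLS] + 2 [SEP]
  assert_that(budget >= 1, "max_len too small for metadata tail")
  if (length(residues) > budget) residues <- residues[seq_len(budget)]
  res_ids <- unname(vocab_id(vocab, residues))
  ids <- c(vocab$ids[["[CLS]"]], res_ids, vocab$ids[["[SEP]"]],
           meta_ids, vocab$ids[["[SEP]"]])
  category <- c("special", rep("residue", length(res_ids)), "special",
                rep("metadata", n_meta), "special")
  n_real <- length(ids)
  if (n_real < max_len) {
    ids <- c(ids, rep(vocab$ids[["[PAD]"]], max_len - n_real))
    category <- c(category, rep("special", max_len - n_real))
  }
  structure(list(ids = as.integer(ids),
                 pad_mask = seq_len(max_len) <= n_real,
                 category = category,
                 source_id = record$id %||% NA_character_),
            class = "encoded_seq")
}

#' Decode token ids
#'
#' @param ids Integer vector of 0-based token ids.
#' @param vocab `bcr_vocab`.
#' @return Character vector of token strings.
#' @export
decode <- function(ids, vocab) {
  assert_that(all(ids >= 0 & ids < vocab$size), "token id out of vocabulary range")
  vocab$tokens[ids + 1L]
}

#' Encode a set of records into matrices
#'
#' @param records data.frame of records.
#' @param vocab `bcr_vocab`.
#' @param mode,max_len As in [encode()].
#' @return list with integer matrix `ids` (n x max_len, 0-based), logical
#'   `pad_mask`, character `category` matrix, `source_id` vector and
#'   `max_len`.
#' @export
encode_batch <- function(records, vocab, mode = "full_length", max_len = 148L) {
  encs <- lapply(seq_len(nrow(records)), function(i) {
    encode(records[i, , drop = FALSE], vocab, mode = mode, max_len = max_len)
  })
  list(ids = do.call(rbind, lapply(encs, `[[`, "ids")),
       pad_mask = do.call(rbind, lapply(encs, `[[`, "pad_mask")),
       category = do.call(rbind, lapply(encs, `[[`, "category")),
       source_id = vapply(encs, `[[`, character(1), "source_id"),
       max_len = max_len)
}

#' Serialize / load a vocabulary as a two-column text file
#'
#' @param vocab `bcr_vocab`.
#' @param path Output file (tab-separated token, id).
#' @return `path` invisibly, or the reloaded vocabulary.
#' @export
write_vocabulary <- function(vocab, path) {
  write.table(data.frame(token = vocab$tokens, id = seq_along(vocab$tokens) - 1L),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  tokens <- df$token[order(df$id)]
  assert_that(identical(tokens[1:5], SPECIAL_TOKENS),
              "vocabulary file does not start with the special-token block")
  aa <- tokens[6:25]
  rest <- tokens[-(1:25)]
  iso <- rest[rest %in% ISOTYPES]
  genes <- rest[!(rest %in% ISOTYPES)]
  build_vocabulary(genes, iso)
}

#' @noRd
vocab_hash <- function(vocab) {
  # order-sensitive light-weight hash of the token list (provenance check)
  sum(as.numeric(utf8ToInt(paste(vocab$tokens, collapse = "|"))) *
        (seq_len(nchar(paste(vocab$tokens, collapse = "|"))) %% 97 + 1)) %% 2^31
}
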