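# Subword tokenization for the text encoder. Supports byte-pair-encoding
# merge tables in the standard two-token-per-line format; without a merge
# table it falls back to whole-word lookup with character-level splitting of
# out-of-vocabulary words, which is what the shipped toy vocabulary uses.
# Ids are 1-based; positions 1..4 are reserved for the special tokens.

PAD_ID <- 1L
START_ID <- 2L
END_ID <- 3L
UNK_ID <- 4L

special_tokens <- function() c("<pad>", "<start>", "<end>", "<unk>")

#' Build a vocabulary from a corpus of texts
#'
#' The vocabulary contains the four special tokens, all single characters
#' seen in the corpus (fallback units), and all whole lowercased words.
#'
#' @param texts Character vector of example texts.
#' @param merges Optional character vector of byte-pair merges, each a line
#'   `"tok1 tok2"` in priority order (as in standard BPE merge files). When
#'   supplied, words are segmented by applying the merges; the merge
#'   products are added to the vocabulary.
#' @return A `ceus_vocab` object with `tokens` (character vector; id =
#'   position) and optional `merges`.
#' @export
build_vocab <- function(texts, merges = NULL) {
  words <- unlist(lapply(tolower(texts), split_words))
  chars <- unique(unlist(strsplit(words, "", fixed = TRUE)))
  toks <- c(special_tokens(), sort(chars), sort(unique(words)))
  if (!is.null(merges)) {
    prods <- vapply(strsplit(merges, " ", fixed = TRUE),
                    function(p) paste0(p[1], p[2]), character(1))
    toks <- unique(c(toks, prods))
  }
  structure(list(tokens = toks, merges = merges), class = "ceus_vocab")
}

#' Read a vocabulary (and optional merge table) from disk
#'
#' @param vocab_path JSON file with a `tokens` array (and optionally
#'   `merges`), or a plain text file with one token per line.
#' @param merges_path Optional standard BPE merges file (one merge per line,
#'   `#`-prefixed header lines ignored).
#' @return A `ceus_vocab`.
#' @export
read_vocab <- function(vocab_path, merges_path = NULL) {
  if (grepl("\\.json$", vocab_path)) {
    x <- jsonlite::read_json(vocab_path, simplifyVector = TRUE)
    toks <- x$tokens
    merges <- x$merges
  } else {
    toks <- readLines(vocab_path)
    merges <- NULL
  }
  if (!is.null(merges_path)) {
    merges <- readLines(merges_path)
    merges <- merges[!grepl("^#", merges) & nzchar(merges)]
  }
  if (!identical(toks[1:4], special_tokens()))
    toks <- c(special_tokens(), setdiff(toks, special_tokens()))
  structure(list(tokens = toks, merges = merges), class = "ceus_vocab")
}

split_words <- function(text) {
  m <- gregexpr("[a-z0-9]+|[^a-z0-9[:space:]]", text)
  regmatches(text, m)[[1]]
}

# Apply BPE merges to one word: start from characters with an end-of-word
# marker on the last unit, repeatedly apply the highest-priority merge.
bpe_segment <- function(word, merges) {
  units <- strsplit(word, "", fixed = TRUE)[[1]]
  if (length(units) == 0L) return(character(0))
  units[length(units)] <- paste0(units[length(units)], "</w>")
  rank <- seq_along(merges)
  names(rank) <- merges
  repeat {
    if (length(units) < 2L) break
    pairs <- paste(units[-length(units)], units[-1])
    r <- rank[pairs]
    if (all(is.na(r))) break
    k <- which.min(r)
    units <- c(units[seq_len(k - 1L)],
               paste0(units[k], units[k + 1L]),
               if (k + 1L < length(units)) units[(k + 2L):length(units)])
  }
  units
}

#' Tokenize a text into padded token ids
#'
#' Lowercases, splits into words and punctuation, maps each word through the
#' vocabulary (BPE segmentation when a merge table is present; otherwise
#' whole-word lookup with character fallback), and wraps the sequence in
#' start/end markers, truncating to `context_length` with the end marker
#' preserved. Trailing positions are padded.
#'
#' @param text Non-empty string.
#' @param vocab A `ceus_vocab`.
#' @param context_length Maximum sequence length including markers.
#' @return A `token_ids` list with `ids` (integer vector of length
#'   `context_length`) and `len` (position of the end marker).
#' @export
tokenize <- function(text, vocab, context_length = 77) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("`text` must be a non-empty string")
  stopifnot(inherits(vocab, "ceus_vocab"))
  words <- split_words(tolower(text))
  lookup <- function(tok) {
    id <- match(tok, vocab$tokens)
    if (is.na(id)) UNK_ID else id
  }
  ids <- unlist(lapply(words, function(w) {
    if (!is.null(vocab$merges)) {
      vapply(bpe_segment(w, vocab$merges), lookup, integer(1))
    } else {
      id <- match(w, vocab$tokens)
      if (!is.na(id)) return(id)
      # character fallback for out-of-vocabulary words
      vapply(strsplit(w, "", fixed = TRUE)[[1]], lookup, integer(1))
    }
  }), use.names = FALSE)
  ids <- c(START_ID, ids)
  if (length(ids) > context_length - 1L) ids <- ids[seq_len(context_length - 1L)]
  ids <- c(ids, END_ID)
  len <- length(ids)
  ids <- c(ids, rep(PAD_ID, context_length - len))
  structure(list(ids = ids, len = len), class = "token_ids")
}

vocab_size <- function(vocab) length(vocab$tokens)
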