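#' Dictionaries for EMR text normalization
#'
#' Bundles the three resources the preprocessing stage needs: a stop-word
#' list, a synonym map (variant term -> canonical term, e.g. "HBV" ->
#' "hepatitis_B") and a user dictionary of multi-token domain terms the
#' tokenizer must keep whole (e.g. "type 2 diabetes").
#'
#' The synonym map must be acyclic after one application: a canonical term may
#' not itself appear as a variant, which makes [normalize_text()] idempotent.
#'
#' @param stopwords character vector of terms to drop.
#' @param synonyms named character vector; names are variant terms, values the
#'   canonical replacements.
#' @param user_terms character vector of (possibly multi-word) terms.
#' @return An object of class `specrec_dictionaries`.
#' @export
dictionaries <- function(stopwords = character(), synonyms = character(),
                         user_terms = character()) {
  stopwords <- as.character(stopwords)
  user_terms <- as.character(user_terms)
  if (length(synonyms)) {
    if (is.null(names(synonyms)) || any(!nzchar(names(synonyms))))
      stop("`synonyms` must be a named character vector (variant -> canonical)")
    synonyms <- vapply(synonyms, as.character, character(1))
    if (any(!nzchar(synonyms)))
      stop("synonym canonical terms must be non-empty")
    bad <- intersect(unname(synonyms), names(synonyms))
    if (length(bad))
      stop("synonym map is not acyclic: canonical term(s) also variants: ",
           paste(bad, collapse = ", "))
  } else {
    synonyms <- stats::setNames(character(), character())
  }
  if (any(!nzchar(stopwords)) || any(!nzchar(user_terms)))
    stop("dictionary entries must be non-empty strings")
  structure(list(stopwords = stopwords, synonyms = synonyms,
                 user_terms = user_terms),
            class = "specrec_dictionaries")
}

#' Read dictionaries from plain-text files
#'
#' Stop-word and user-term files hold one entry per line; the synonym file is
#' a two-column TSV `variant<TAB>canonical`. Missing paths give empty
#' resources.
#'
#' @param stopwords_file,synonyms_file,user_terms_file file paths or `NULL`.
#' @return A `specrec_dictionaries` object.
#' @export
read_dictionaries <- function(stopwords_file = NULL, synonyms_file = NULL,
                              user_terms_file = NULL) {
  read_lines <- function(path) {
    if (is.null(path) || !file.exists(path)) return(character())
    x <- readLines(path, encoding = "UTF-8", warn = FALSE)
    x[nzchar(trimws(x))]
  }
  syn <- character()
  if (!is.null(synonyms_file) && file.exists(synonyms_file)) {
    lines <- read_lines(synonyms_file)
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      if (any(lengths(parts) != 2))
        stop("synonym file must be two tab-separated columns")
      syn <- stats::setNames(vapply(parts, `[`, character(1), 2),
                             vapply(parts, `[`, character(1), 1))
    }
  }
  dictionaries(stopwords = read_lines(stopwords_file), synonyms = syn,
               user_terms = read_lines(user_terms_file))
}

#' Replace synonymous terms by their canonical form
#'
#' Applies the synonym map longest-variant-first in a single pass so that
#' chained rewrites cannot occur; the operation is idempotent. Matches are
#' bounded by word boundaries (a variant never matches inside a longer word).
#'
#' @param text character vector of raw text.
#' @param synonyms named character vector (variant -> canonical), or a
#'   `specrec_dictionaries` object.
#' @return character vector of the same length.
#' @examples
#' normalize_text("HBV positive", c(HBV = "hepatitis_B"))
#' @export
normalize_text <- function(text, synonyms) {
  if (inherits(synonyms, "specrec_dictionaries")) synonyms <- synonyms$synonyms
  if (!length(synonyms) || !length(text)) return(text)
  variants <- names(synonyms)[order(-nchar(names(synonyms)))]
  for (v in variants) {
    pat <- paste0("(?<![\\p{L}\\p{N}_])", gsub("([][{}()+*^$|\\\\?.])",
                                               "\\\\\\1", v),
                  "(?![\\p{L}\\p{N}_])")
    text <- gsub(pat, synonyms[[v]], text, perl = TRUE)
  }
  text
}

# default whitespace tokenizer; the plugin point for language-specific
# segmenters (e.g. a Chinese segmentation backend) is the `tokenizer`
# argument of tokenize()/build_corpus()
.split_ws <- function(text) {
  out <- strsplit(trimws(text), "\\s+", perl = TRUE)[[1]]
  out[nzchar(out)]
}

#' Tokenize normalized text
#'
#' Splits text into tokens, recognizes user-dictionary terms as single tokens
#' (longest match first), and filters out stop words plus tokens carrying no
#' letter at all (bare numbers, punctuation).
#'
#' @param text a single character string.
#' @param dicts a `specrec_dictionaries` object.
#' @param tokenizer optional function `text -> character vector` producing the
#'   raw word stream; defaults to whitespace splitting.
#' @return character vector of tokens (possibly empty).
#' @examples
#' d <- dictionaries(stopwords = "with", user_terms = "type 2 diabetes")
#' tokenize("type 2 diabetes , with cough", d)
#' @export
tokenize <- function(text, dicts = dictionaries(), tokenizer = NULL) {
  stopifnot(inherits(dicts, "specrec_dictionaries"), length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  words <- if (is.null(tokenizer)) .split_ws(text) else tokenizer(text)
  if (!length(words)) return(character())

  # greedy longest-match merge of user terms
  if (length(dicts$user_terms)) {
    terms <- strsplit(dicts$user_terms, "\\s+", perl = TRUE)
    terms <- terms[order(-lengths(terms))]
    out <- character(0)
    i <- 1L
    n <- length(words)
    while (i <= n) {
      matched <- FALSE
      for (tm in terms) {
        L <- length(tm)
        if (i + L - 1L <= n && identical(words[i:(i + L - 1L)], tm)) {
          out <- c(out, paste(tm, collapse = " "))
          i <- i + L
          matched <- TRUE
          break
        }
      }
      if (!matched) {
        out <- c(out, words[i])
        i <- i + 1L
      }
    }
    words <- out
  }

  words <- words[grepl("\\p{L}", words, perl = TRUE)]  # drop numbers/symbols
  words[!(words %in% dicts$stopwords)]
}

#' Read a consultation-record CSV
#'
#' Expected header: `patient_id,specialist_id,department,date,text` with
#' ISO-8601 dates.
#'
#' @param path CSV file path.
#' @return A tibble of consultation records.
#' @export
read_consultations <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  need <- c("patient_id", "specialist_id", "department", "date", "text")
  if (!all(need %in% names(df)))
    stop("consultations CSV must have columns: ", paste(need, collapse = ", "))
  df$date <- as.Date(df$date)
  tibble::as_tibble(df[need])
}

#' Build a tokenized corpus from consultation records
#'
#' Drops invalid records (empty ids, unparseable dates, empty text), removes
#' exact duplicates (all five fields equal -- two patients may legitimately
#' share a diagnosis sentence, so text equality alone is not a duplicate),
#' normalizes synonyms, tokenizes, and assembles the document set with its
#' vocabulary. Documents that end up with zero tokens are dropped.
#'
#' @param records data frame with columns `patient_id`, `specialist_id`,
#'   `department`, `date`, `text`.
#' @param dicts a `specrec_dictionaries` object.
#' @param tokenizer optional tokenizer plugin, see [tokenize()].
#' @return An object of class `specrec_corpus`: list with `documents` (named
#'   list of token vectors), `meta` (tibble keyed by `doc_id`) and
#'   `vocabulary`.
#' @export
build_corpus <- function(records, dicts = dictionaries(), tokenizer = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("patient_id", "specialist_id", "department", "date", "text")
  stopifnot(all(need %in% names(records)))
  records$date <- as.Date(records$date)

  ok <- nzchar(records$patient_id) & !is.na(records$patient_id) &
    nzchar(records$specialist_id) & !is.na(records$specialist_id) &
    !is.na(records$date) &
    !is.na(records$text) & nzchar(trimws(records$text))
  records <- records[ok, need, drop = FALSE]
  records <- records[!duplicated(records), , drop = FALSE]
  if (nrow(records) == 0)
    stop("no valid consultation records: corpus would be empty")

  norm <- normalize_text(records$text, dicts)
  toks <- lapply(norm, tokenize, dicts = dicts, tokenizer = tokenizer)
  keep <- lengths(toks) > 0
  records <- records[keep, , drop = FALSE]
  toks <- toks[keep]
  if (!length(toks))
    stop("all documents empty after tokenization: corpus would be empty")

  doc_id <- sprintf("d%05d", seq_along(toks))
  names(toks) <- doc_id
  meta <- tibble::tibble(doc_id = doc_id,
                         patient_id = records$patient_id,
                         specialist_id = records$specialist_id,
                         department = records$department,
                         date = records$date)
  structure(list(documents = toks, meta = meta,
                 vocabulary = sort(unique(unlist(toks, use.names = FALSE)))),
            class = "specrec_corpus")
}

#' @export
print.specrec_corpus <- function(x, ...) {
  cat("<specrec_corpus> ", length(x$documents), " documents, ",
      length(x$vocabulary), " vocabulary terms\n", sep = "")
  invisible(x)
}
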