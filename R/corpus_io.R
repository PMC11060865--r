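#' Read a corpus of abstracts
#'
#' Reads abstracts from JSON-lines or tab-separated files into a corpus
#' data frame. Each record carries a unique `id`, the abstract `text`, an
#' optional class `label` (`"patho"` / `"nonpatho"`; anything missing becomes
#' `"unlabeled"`), and optional species tags.
#'
#' JSONL files hold one object per line with keys `id`, `text` and optionally
#' `label` and `species` (string or array of strings). TSV files have a header
#' line `id<TAB>text[<TAB>label][<TAB>species]`; multiple species tags in one
#' cell are separated by commas or semicolons.
#'
#' @param path Path to the corpus file.
#' @param format Either `"jsonl"` or `"tsv"`.
#' @return A data frame with columns `id` (character), `text` (character),
#'   `label` (character, one of `"patho"`, `"nonpatho"`, `"unlabeled"`) and
#'   `species` (list of character vectors, possibly empty).
#' @examples
#' tf <- tempfile(fileext = ".jsonl")
#' writeLines(c(
#'   '{"id":"a","text":"APOE in Alzheimer disease","label":"patho"}',
#'   '{"id":"b","text":"a study of crop yields"}'
#' ), tf)
#' corp <- read_abstracts(tf, "jsonl")
#' corp$label
#' @export
read_abstracts <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
        error = function(e) stop("malformed JSONL record at line ", i, ": ",
          conditionMessage(e), call. = FALSE))
      if (is.null(rec$id) || is.null(rec$text))
        stop("malformed JSONL record at line ", i, ": missing id or text",
          call. = FALSE)
      list(id = as.character(rec$id), text = as.character(rec$text),
        label = if (is.null(rec$label)) NA_character_ else as.character(rec$label),
        species = if (is.null(rec$species)) character(0) else
          tolower(as.character(unlist(rec$species))))
    })
    corpus <- data.frame(
      id = vapply(recs, `[[`, "", "id"),
      text = vapply(recs, `[[`, "", "text"),
      label = vapply(recs, `[[`, "", "label"),
      stringsAsFactors = FALSE)
    corpus$species <- I(lapply(recs, `[[`, "species"))
  } else {
    tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
      colClasses = "character", check.names = FALSE)
    if (!all(c("id", "text") %in% names(tab)))
      stop("TSV corpus must have 'id' and 'text' columns")
    corpus <- data.frame(id = tab$id, text = tab$text,
      label = if ("label" %in% names(tab)) tab$label else NA_character_,
      stringsAsFactors = FALSE)
    corpus$species <- I(if ("species" %in% names(tab))
      lapply(tab$species, function(s) {
        s <- tolower(trimws(strsplit(s, "[,;]")[[1]]))
        s[nzchar(s)]
      }) else rep(list(character(0)), nrow(tab)))
  }
  corpus$label[is.na(corpus$label) | !nzchar(corpus$label)] <- "unlabeled"
  bad <- setdiff(unique(corpus$label), c("patho", "nonpatho", "unlabeled"))
  if (length(bad))
    stop("unknown label value(s): ", paste(bad, collapse = ", "))
  dup <- corpus$id[duplicated(corpus$id)]
  if (length(dup))
    stop("duplicate abstract id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(corpus$id))) stop("empty abstract id")
  if (any(!nzchar(corpus$text)))
    stop("empty text for id(s): ",
      paste(corpus$id[!nzchar(corpus$text)], collapse = ", "))
  rownames(corpus) <- NULL
  corpus
}

#' Write a corpus of abstracts
#'
#' Inverse of [read_abstracts()]; mainly used by the command-line interface
#' and the synthetic-corpus tooling.
#'
#' @param corpus Corpus data frame as returned by [read_abstracts()].
#' @param path Output file path.
#' @param format `"jsonl"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_abstracts <- function(corpus, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- list(id = corpus$id[i], text = corpus$text[i])
      if (corpus$label[i] != "unlabeled") rec$label <- corpus$label[i]
      sp <- corpus$species[[i]]
      if (length(sp)) rec$species <- sp
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, "")
    writeLines(lines, path)
  } else {
    tab <- data.frame(id = corpus$id, text = corpus$text, label = corpus$label,
      species = vapply(corpus$species, paste, "", collapse = ","),
      stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a named-entity lexicon
#'
#' Loads a gazetteer of (possibly multi-word) entity surface forms used to
#' merge named-entity n-grams into single tokens during preprocessing.
#' The file is TSV with columns `surface_form<TAB>entity_type` (no header
#' required; a header row naming the two columns is tolerated).
#'
#' @param path Path to the lexicon TSV.
#' @return An entity lexicon: data frame with columns `surface_form`
#'   (lowercase) and `entity_type` (one of gene, disease, tissue, celltype,
#'   other).
#' @export
read_lexicon <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
    colClasses = "character")
  if (ncol(tab) < 2) stop("lexicon TSV needs two columns: surface_form, entity_type")
  if (identical(tolower(tab[1, 1]), "surface_form")) tab <- tab[-1, , drop = FALSE]
  entity_lexicon(tab[[1]], tab[[2]])
}

#' Construct an entity lexicon
#'
#' @param surface_form Character vector of entity names; multi-word names are
#'   space-separated. Stored lowercase.
#' @param entity_type Character vector (recycled) of entity types:
#'   `"gene"`, `"disease"`, `"tissue"`, `"celltype"` or `"other"`.
#' @return Data frame of class `entity_lexicon`.
#' @examples
#' lex <- entity_lexicon(c("adipose tissue", "APOE"), c("tissue", "gene"))
#' @export
entity_lexicon <- function(surface_form, entity_type = "other") {
  surface_form <- tolower(trimws(surface_form))
  entity_type <- rep_len(as.character(entity_type), length(surface_form))
  ok_types <- c("gene", "disease", "tissue", "celltype", "other")
  if (!all(entity_type %in% ok_types))
    stop("entity_type must be one of: ", paste(ok_types, collapse = ", "))
  if (any(!nzchar(surface_form))) stop("empty surface form in lexicon")
  lex <- data.frame(surface_form = surface_form, entity_type = entity_type,
    stringsAsFactors = FALSE)
  lex <- unique(lex)
  rownames(lex) <- NULL
  class(lex) <- c("entity_lexicon", "data.frame")
  lex
}

#' Default English stop-word list
#'
#' A fixed list of common English function words shipped with the package so
#' preprocessing is reproducible. Users can pass their own list to
#' [preprocess()].
#'
#' @return Lowercase character vector of stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "pathomine")
  if (!nzchar(path)) stop("packaged stop-word list not found")
  readLines(path, warn = FALSE)
}

#' Species keywords indicating human-relatable abstracts
#'
#' The keyword set used to retain abstracts relatable to human subjects:
#' human, boy, girl, children, man, woman, men, women, patients, patient.
#'
#' @return Lowercase character vector.
#' @export
species_keywords <- function() {
  c("human", "boy", "girl", "children", "man", "woman", "men", "women",
    "patients", "patient")
}

# Strip leading/trailing punctuation from tokens, keeping interior characters
# (hyphens, underscores, apostrophes) so entity names and merged tokens survive.
strip_edge_punct <- function(tokens) {
  gsub("^[^[:alnum:]_]+|[^[:alnum:]_]+$", "", tokens)
}

# Index a lexicon for greedy longest-match lookup: map from first token of each
# surface form to the list of its token sequences, longest first.
index_lexicon <- function(lexicon) {
  seqs <- strsplit(unique(lexicon$surface_form), "[[:space:]]+")
  idx <- new.env(parent = emptyenv())
  for (s in seqs) {
    key <- s[[1]]
    cur <- if (!is.null(idx[[key]])) idx[[key]] else list()
    cur[[length(cur) + 1L]] <- s
    idx[[key]] <- cur
  }
  # longest candidate first so greedy matching is maximal
  for (key in ls(idx)) {
    cand <- idx[[key]]
    idx[[key]] <- cand[order(-lengths(cand))]
  }
  idx
}

# Greedy longest-match, left-to-right merge of lexicon n-grams into
# underscore-joined single tokens.
merge_entities <- function(tokens, lex_index) {
  n <- length(tokens)
  if (n == 0L) return(tokens)
  out <- character(n)
  m <- 0L
  i <- 1L
  while (i <= n) {
    cands <- lex_index[[tokens[[i]]]]
    hit <- 0L
    if (!is.null(cands)) {
      for (s in cands) {
        len <- length(s)
        if (i + len - 1L <= n && identical(tokens[i:(i + len - 1L)], s)) {
          hit <- len
          break
        }
      }
    }
    m <- m + 1L
    if (hit > 0L) {
      out[[m]] <- paste(tokens[i:(i + hit - 1L)], collapse = "_")
      i <- i + hit
    } else {
      out[[m]] <- tokens[[i]]
      i <- i + 1L
    }
  }
  out[seq_len(m)]
}

#' Preprocess abstract text into tokens
#'
#' Lowercases, tokenizes on whitespace, merges multi-word named entities into
#' single underscore-joined tokens (greedy longest match, left to right, before
#' stop-word removal so entity names containing function words survive), strips
#' leading/trailing punctuation, and drops punctuation-only tokens and stop
#' words. The result is the token stream used for embedding training; the
#' bigram "adipose tissue" becomes the single token `"adipose_tissue"` when
#' the lexicon lists it.
#'
#' Re-running `preprocess` on its own (space-joined) output is a no-op, and
#' splitting a merged token on underscores recovers the surface form that
#' matched.
#'
#' @param text A single character string (an abstract).
#' @param stopwords Lowercase character vector of stop words; defaults to the
#'   packaged list.
#' @param lexicon Optional entity lexicon ([entity_lexicon()]); `NULL` skips
#'   entity merging.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' lex <- entity_lexicon("adipose tissue", "tissue")
#' preprocess("Leptin signaling in adipose tissue.", lexicon = lex)
#' @export
preprocess <- function(text, stopwords = default_stopwords(), lexicon = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  tokens <- strsplit(tolower(text), "[[:space:]]+")[[1]]
  tokens <- strip_edge_punct(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (!is.null(lexicon)) {
    lex_index <- if (is.environment(lexicon)) lexicon else index_lexicon(lexicon)
    tokens <- merge_entities(tokens, lex_index)
  }
  tokens <- tokens[!(tokens %in% stopwords)]
  tokens
}

#' Preprocess every abstract in a corpus
#'
#' @param corpus Corpus data frame (see [read_abstracts()]).
#' @inheritParams preprocess
#' @return Named list of token vectors, one per abstract, keyed by abstract id.
#' @export
tokenize_corpus <- function(corpus, stopwords = default_stopwords(),
                            lexicon = NULL) {
  lex_index <- if (is.null(lexicon)) NULL else index_lexicon(lexicon)
  toks <- lapply(corpus$text, preprocess, stopwords = stopwords,
    lexicon = lex_index)
  names(toks) <- corpus$id
  toks
}

#' Filter abstracts by species keywords
#'
#' Retains abstracts relatable to a keyword set (by default the human-related
#' keywords of [species_keywords()]). When an abstract carries species tags the
#' tags are matched; otherwise its token set is matched. Any single match
#' retains the abstract; input order is preserved.
#'
#' @param corpus Corpus data frame.
#' @param keywords Lowercase keywords; defaults to [species_keywords()].
#' @param stopwords Stop words used when falling back to token matching.
#' @return The retained subset of `corpus`.
#' @export
filter_species <- function(corpus, keywords = species_keywords(),
                           stopwords = default_stopwords()) {
  if (length(keywords) == 0L) return(corpus[integer(0), , drop = FALSE])
  keep <- vapply(seq_len(nrow(corpus)), function(i) {
    tags <- corpus$species[[i]]
    if (length(tags)) {
      any(tags %in% keywords)
    } else {
      any(preprocess(corpus$text[i], stopwords = stopwords) %in% keywords)
    }
  }, logical(1))
  out <- corpus[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write tokenized abstracts as JSON lines
#'
#' One object per line with keys `id` and `tokens`.
#'
#' @param tokens Named list of token vectors (see [tokenize_corpus()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tokens <- function(tokens, path) {
  lines <- vapply(names(tokens), function(id) {
    jsonlite::toJSON(list(id = id, tokens = tokens[[id]]), auto_unbox = TRUE)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read tokenized abstracts from JSON lines
#'
#' @param path Path written by [write_tokens()].
#' @return Named list of token vectors.
#' @export
read_tokens <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  toks <- lapply(recs, function(r) as.character(r$tokens))
  names(toks) <- vapply(recs, function(r) as.character(r$id), "")
  toks
}
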