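# Registries for pluggable translators and lemmatizers. Both contracts are
# pure, vectorized character -> character functions; "identity" is always
# available as a baseline.
.vax_registry <- new.env(parent = emptyenv())
.vax_registry$translators <- list(identity = function(x) x)
.vax_registry$lemmatizers <- list(identity = function(x) x)

#' Register a translator or lemmatizer plug-in
#'
#' Translators map whole comment texts; lemmatizers map individual tokens to
#' their dictionary form. Both must be pure, vectorized
#' character -> character functions. Machine translation backends (e.g. an
#' external API) and POS-aware lemmatizers can be plugged in here; the
#' package itself ships only the `"identity"` baseline plus helpers for
#' table-driven lookup components.
#'
#' @param name Registry name.
#' @param fn Vectorized character -> character function.
#' @return `name`, invisibly.
#' @export
register_translator <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  .vax_registry$translators[[name]] <- fn
  invisible(name)
}

#' @rdname register_translator
#' @export
register_lemmatizer <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  .vax_registry$lemmatizers[[name]] <- fn
  invisible(name)
}

resolve_component <- function(x, kind) {
  if (is.function(x)) return(x)
  reg <- .vax_registry[[kind]]
  if (!is.character(x) || length(x) != 1 || is.null(reg[[x]])) {
    abort_config(paste0("Unknown ", sub("s$", "", kind), ": '",
                        paste(x, collapse = ","), "'"))
  }
  reg[[x]]
}

#' Build a lookup-table lemmatizer or translator
#'
#' `lookup_lemmatizer()` maps listed tokens to their lemma and leaves other
#' tokens unchanged. `lookup_translator()` does the same word-by-word on
#' whitespace-separated text, a deliberately simple stand-in useful for
#' testing the translation seam.
#'
#' @param map Named character vector (names = source forms).
#' @return A vectorized character -> character function.
#' @export
lookup_lemmatizer <- function(map) {
  stopifnot(is.character(map), !is.null(names(map)))
  function(x) {
    hit <- x %in% names(map)
    x[hit] <- unname(map[x[hit]])
    x
  }
}

#' @rdname lookup_lemmatizer
#' @export
lookup_translator <- function(map) {
  word_map <- lookup_lemmatizer(map)
  function(x) {
    vapply(x, function(s) {
      if (is.na(s) || s == "") return(s)
      paste(word_map(strsplit(s, "\\s+")[[1]]), collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  }
}

#' Preprocessing configuration
#'
#' Bundles the stopword list and the translator/lemmatizer plug-ins used by
#' [tokenize_normalize()] and [preprocess_corpus()].
#'
#' @param stopwords Character vector of lowercase stopword terms; defaults to
#'   the packaged English list (see [default_stopwords()]).
#' @param lemmatizer Registry name or function; default `"identity"`.
#' @param translator Registry name or function; default `"identity"`.
#' @return A `vax_preprocess_config` list.
#' @export
preprocess_config <- function(stopwords = default_stopwords(),
                              lemmatizer = "identity",
                              translator = "identity") {
  if (length(stopwords) == 0) {
    abort_config("The stopword list must be non-empty in the default profile.")
  }
  structure(
    list(stopwords = tolower(stopwords),
         lemmatizer = lemmatizer, translator = translator),
    class = "vax_preprocess_config")
}

#' The packaged English stopword list
#'
#' A fixed list of common English function words, versioned inside the
#' package so tokenization results do not drift with external library
#' updates. One lowercase term per line on disk.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "vaxtalk")
  readLines(path, encoding = "UTF-8")
}

#' Strip social-media markup from text
#'
#' Removes URLs (scheme-prefixed or www-prefixed), #hashtags, @usernames,
#' and emoji / pictographic characters (matched by Unicode property classes,
#' including skin-tone modifiers, variation selectors, and zero-width
#' joiners), then collapses whitespace. Hashtag tokens are deleted whole,
#' not de-hashed. All remaining text keeps its order.
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @export
strip_markup <- function(text) {
  out <- stringr::str_remove_all(text, "(?i)(?:https?://|www\\.)\\S+")
  out <- stringr::str_remove_all(out, "[#@][\\p{L}\\p{N}_]+")
  out <- stringr::str_remove_all(out, "[\\p{So}\\p{Sk}\\x{200D}\\x{FE0F}\\x{20E3}]")
  stringr::str_squish(out)
}

#' Translate comment text through a pluggable translator
#'
#' The default `"identity"` translator returns its input verbatim; real
#' machine-translation backends are registered with [register_translator()].
#'
#' @param text Character vector.
#' @param translator Registry name or function.
#' @return Translated character vector.
#' @export
translate_text <- function(text, translator = "identity") {
  fn <- resolve_component(translator, "translators")
  fn(text)
}

#' Normalize text into a token sequence
#'
#' Applies, in order: lowercasing, deletion of digit / punctuation / symbol
#' characters, whitespace tokenization, stopword removal, and lemmatization.
#' Stopwords are removed before lemmatization, following the listed order of
#' the preprocessing steps; the order matters for inflected stopwords and is
#' therefore fixed and documented.
#'
#' @param text A single string (already markup-stripped and translated when
#'   used inside [preprocess_corpus()]).
#' @param config A `vax_preprocess_config`.
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_normalize <- function(text, config = preprocess_config()) {
  lemmatize <- resolve_component(config$lemmatizer, "lemmatizers")
  low <- stringr::str_to_lower(text)
  low <- stringr::str_remove_all(low, "[\\p{N}\\p{P}\\p{S}]")
  tokens <- stringr::str_split_1(stringr::str_squish(low), stringr::fixed(" "))
  tokens <- tokens[nzchar(tokens)]
  tokens <- tokens[!tokens %in% config$stopwords]
  if (length(tokens) == 0) return(character())
  lemmatize(tokens)
}

#' Preprocess a whole corpus into token documents
#'
#' Runs the full preprocessing pipeline per comment — markup stripping,
#' translation, token normalization — and returns one token document per
#' comment, in corpus order. Comments whose text reduces to nothing are
#' retained as empty token documents (they contribute zero terms
#' downstream).
#'
#' @param x A `vax_corpus`.
#' @param config A `vax_preprocess_config`.
#' @return A tibble (`vax_tokens`) with columns `comment_id`, `label`, and
#'   list-column `tokens`.
#' @export
preprocess_corpus <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "vax_corpus"))
  cm <- x$comments
  stripped <- strip_markup(cm$text)
  translated <- translate_text(stripped, config$translator)
  toks <- lapply(translated, tokenize_normalize, config = config)
  out <- tibble(comment_id = cm$id, label = cm$label, tokens = toks)
  class(out) <- c("vax_tokens", class(out))
  out
}
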