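# Protected-token patterns: user mentions, URLs, email addresses.
.pp_patterns <- function() {
  c(url = "[a-z][a-z0-9+.-]*://[^[:space:]]+",
    email = "[A-Za-z0-9._%+-]+@[A-Za-z0-9.-]+\\.[A-Za-z]{2,}",
    user_id = "@[A-Za-z0-9_]+")
}

.emoticon_sets <- list(positive = c(":)", ":D"), negative = c(":(", ":/"))

#' Signed emoticon sets
#'
#' The two small signed emoticon vocabularies used throughout the package
#' (corpus generation, POS tagging, sentiment features).
#' @return A list with character vectors `positive` and `negative`.
#' @export
emoticon_sets <- function() .emoticon_sets

# token regex: protected patterns first, then emoticons, punctuation, catchall
.token_rx <- function() {
  emo <- stringr::str_replace_all(unlist(.emoticon_sets), "([()/\\\\.+*?\\[\\]^$|])", "\\\\\\1")
  paste(c(.pp_patterns(), emo, "[!?.,;:]", "[^[:space:]!?.,;:]+"), collapse = "|")
}

#' Extract protected proper-noun tokens
#'
#' Finds user mentions (`@`-prefixed alphanumerics), URLs
#' (`scheme://...`) and email addresses in a post, replaces each maximal
#' match with a placeholder (`PTK001`, `PTK002`, ...) and returns the
#' protected tokens with their kinds. Masking is reversible via the
#' returned table and is idempotent: running the extraction on its own
#' masked output finds nothing further.
#'
#' @param text A single character string (may be empty).
#' @return A list with `protected` (tibble with columns `placeholder`,
#'   `token`, `kind`) and `masked` (the text with placeholders substituted).
#' @examples
#' extract_proper_nouns("see http://a.b/c now")
#' @export
extract_proper_nouns <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || text == "") {
    return(list(protected = tibble(placeholder = character(),
                                   token = character(), kind = character()),
                masked = if (is.na(text)) "" else text))
  }
  masked <- text
  rows <- list()
  counter <- 0L
  for (kind in names(.pp_patterns())) {
    pat <- .pp_patterns()[[kind]]
    repeat {
      m <- stringr::str_extract(masked, pat)
      if (is.na(m)) break
      counter <- counter + 1L
      ph <- sprintf("PTK%03d", counter)
      masked <- stringr::str_replace(masked, stringr::fixed(m), ph)
      rows[[counter]] <- tibble(placeholder = ph, token = m, kind = kind)
    }
  }
  list(protected = if (length(rows)) dplyr::bind_rows(rows) else
         tibble(placeholder = character(), token = character(),
                kind = character()),
       masked = masked)
}

#' Restore protected tokens into masked text
#' @param masked Masked text from [extract_proper_nouns()].
#' @param protected The matching `protected` table.
#' @return The original text.
#' @export
unmask_text <- function(masked, protected) {
  for (i in seq_len(nrow(protected))) {
    masked <- stringr::str_replace(masked, stringr::fixed(protected$placeholder[i]),
                                   protected$token[i])
  }
  masked
}

#' Tokenize masked post text
#'
#' Splits on whitespace, separates punctuation marks (`! ? . , ; :`) into
#' their own tokens, keeps emoticons intact, and restores placeholders as
#' single (never split) tokens.
#'
#' @param masked Masked text (placeholders in place of protected tokens).
#' @param protected Protected-token table from [extract_proper_nouns()];
#'   every placeholder occurring in `masked` must appear in it.
#' @return Character vector of tokens.
#' @examples
#' tokenize_text("good_1 !! :)")
#' @export
tokenize_text <- function(masked,
                          protected = tibble(placeholder = character(),
                                             token = character(),
                                             kind = character())) {
  stopifnot(is.character(masked), length(masked) == 1L)
  if (is.na(masked) || masked == "") return(character(0))
  toks <- stringr::str_extract_all(masked, .token_rx())[[1]]
  is_ph <- stringr::str_detect(toks, "^PTK\\d{3}$")
  if (any(is_ph)) {
    hit <- match(toks[is_ph], protected$placeholder)
    if (anyNA(hit)) {
      abort("orphan placeholder in masked text: no matching protected token.",
            class = "opinionpulse_processing_error")
    }
    toks[is_ph] <- protected$token[hit]
  }
  toks
}

#' Lexicon-based POS tagging
#'
#' Assigns each token a coarse tag. Emoticons map to `EMO`, single
#' punctuation marks to `PUNCT`, protected proper nouns (mentions, URLs,
#' emails) to `PROPER`, tokens found in the tag lexicon to their lexicon
#' tag, everything else to `OTHER`. The synthetic language ships an exact
#' tag lexicon, so no statistical tagger is needed.
#'
#' @param tokens Character vector of tokens.
#' @param tag_lexicon Data frame with columns `token`, `tag`.
#' @return Character vector of tags, same length as `tokens`.
#' @export
pos_tag <- function(tokens, tag_lexicon) {
  if (length(tokens) == 0L) return(character(0))
  stopifnot(all(c("token", "tag") %in% names(tag_lexicon)))
  tags <- rep("OTHER", length(tokens))
  emo <- tokens %in% unlist(.emoticon_sets)
  punct <- stringr::str_detect(tokens, "^[!?.,;:]$")
  proper_rx <- paste0("^(", paste(.pp_patterns(), collapse = "|"), ")$")
  proper <- stringr::str_detect(tokens, proper_rx)
  hit <- match(tokens, tag_lexicon$token)
  known <- !is.na(hit)
  tags[known] <- tag_lexicon$tag[hit[known]]
  tags[proper] <- "PROPER"
  tags[punct] <- "PUNCT"
  tags[emo] <- "EMO"
  tags
}

#' Tokenize and tag a post corpus
#'
#' Vectorized preprocessing of a whole corpus: protected-token extraction,
#' tokenization and POS tagging in one pass. Equivalent to applying
#' [extract_proper_nouns()], [tokenize_text()] and [pos_tag()] per post.
#'
#' @param posts Post tibble with columns `id` and `text` (e.g. from
#'   [gen_corpus()]).
#' @param tag_lexicon Optional tag lexicon; defaults to the corpus
#'   vocabulary attribute when present.
#' @return The input tibble with list-columns `tokens`, `pos_tags` and
#'   `protected` appended.
#' @export
tokenize_corpus <- function(posts, tag_lexicon = NULL) {
  stopifnot(all(c("id", "text") %in% names(posts)))
  if (is.null(tag_lexicon)) {
    vocab <- attr(posts, "vocab")
    if (is.null(vocab)) {
      abort("`tag_lexicon` missing and corpus carries no vocabulary attribute.",
            class = "opinionpulse_config_error")
    }
    tag_lexicon <- vocab$tag_lexicon
  }
  tok_list <- stringr::str_extract_all(posts$text, .token_rx())
  uniq <- unique(unlist(tok_list, use.names = FALSE))
  utags <- pos_tag(uniq, tag_lexicon)
  proper_rx <- paste0("^(", paste(.pp_patterns(), collapse = "|"), ")$")
  kinds <- dplyr::case_when(
    stringr::str_detect(uniq, paste0("^", .pp_patterns()[["url"]], "$")) ~ "url",
    stringr::str_detect(uniq, paste0("^", .pp_patterns()[["email"]], "$")) ~ "email",
    stringr::str_detect(uniq, paste0("^", .pp_patterns()[["user_id"]], "$")) ~ "user_id",
    TRUE ~ NA_character_)
  out <- posts
  out$tokens <- tok_list
  out$pos_tags <- purrr::map(tok_list, function(t) utags[match(t, uniq)])
  out$protected <- purrr::map(tok_list, function(t) {
    k <- kinds[match(t, uniq)]
    keep <- !is.na(k)
    tibble(token = t[keep], kind = k[keep])
  })
  for (a in c("vocab", "config")) attr(out, a) <- attr(posts, a)
  out
}

#' Write and read tokenized corpora as JSON Lines
#'
#' Tokenized posts are persisted with `tokens` and `pos_tags` arrays
#' appended to each record.
#' @param posts Tokenized post tibble from [tokenize_corpus()].
#' @param path File path.
#' @return `write_tokens_jsonl()` returns `path` invisibly;
#'   `read_tokens_jsonl()` a tibble with list-columns.
#' @export
write_tokens_jsonl <- function(posts, path) {
  recs <- purrr::pmap(list(posts$id, posts$tokens, posts$pos_tags),
                      function(id, tk, tg) list(id = id, tokens = tk,
                                                pos_tags = tg))
  lines <- vapply(recs, function(r) as.character(jsonlite::toJSON(r, auto_unbox = TRUE)),
                  character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tokens_jsonl
#' @export
read_tokens_jsonl <- function(path) {
  recs <- lapply(readLines(path, encoding = "UTF-8"), jsonlite::fromJSON)
  tibble(id = vapply(recs, `[[`, character(1), "id"),
         tokens = lapply(recs, function(r) as.character(r$tokens)),
         pos_tags = lapply(recs, function(r) as.character(r$pos_tags)))
}
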