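#' Bootstrap entity and sentiment-word lexicons from POS and co-occurrence
#'
#' A deterministic stand-in for topic-model-based lexicon induction: nouns
#' with document frequency at least `f_min` become entity candidates, and
#' adjectives/verbs occurring within a `window`-token window of an entity
#' candidate in at least `c_min` posts become sentiment-word candidates.
#' The two sets are disjoint (entity membership wins).
#'
#' @param posts Tokenized post tibble (list-columns `tokens`, `pos_tags`).
#' @param f_min Minimum document frequency for entity candidates.
#' @param c_min Minimum number of posts in which an opinion word must
#'   co-occur near an entity candidate.
#' @param window Co-occurrence window in tokens.
#' @return A list with character vectors `entity_words` and
#'   `sentiment_words`. An empty corpus yields two empty sets.
#' @export
bootstrap_lexicon <- function(posts, f_min = 2, c_min = 2, window = 3) {
  if (nrow(posts) == 0L) {
    return(list(entity_words = character(0), sentiment_words = character(0)))
  }
  stopifnot(all(c("tokens", "pos_tags") %in% names(posts)))
  toks <- unlist(posts$tokens, use.names = FALSE)
  tags <- unlist(posts$pos_tags, use.names = FALSE)
  doc <- rep.int(seq_len(nrow(posts)), lengths(posts$tokens))
  noun <- tags == "NOUN"
  df_noun <- tapply(doc[noun], toks[noun], function(d) length(unique(d)))
  entity_words <- sort(names(df_noun)[df_noun >= f_min])

  cand_counts <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(posts))) {
    tk <- posts$tokens[[i]]
    tg <- posts$pos_tags[[i]]
    ie <- which(tk %in% entity_words)
    if (!length(ie)) next
    ia <- which(tg %in% c("ADJ", "VERB"))
    if (!length(ia)) next
    near <- vapply(ia, function(j) min(abs(j - ie)) <= window, logical(1))
    for (w in unique(tk[ia[near]])) {
      cand_counts[[w]] <- (cand_counts[[w]] %||% 0L) + 1L
    }
  }
  counts <- unlist(as.list(cand_counts))
  sentiment_words <- sort(names(counts)[counts >= c_min])
  sentiment_words <- setdiff(sentiment_words, entity_words)
  list(entity_words = entity_words, sentiment_words = sentiment_words)
}

#' Build an opinion-aware knowledge graph
#'
#' Nodes are the lexicon tokens (entities and sentiment words) observed in
#' the labeled posts. A node's polarity is
#' \eqn{(n_+ - n_-) / (n_+ + n_- + \gamma)}, where \eqn{n_+} (\eqn{n_-}) is
#' the number of positive-labeled (negative-labeled) posts containing the
#' token; edges are undirected within-post co-occurrence counts with no
#' self-loops.
#'
#' @param posts Tokenized post tibble.
#' @param labels Character vector of post labels (`"pos"`, `"neg"`,
#'   `"neu"`), parallel to `posts` rows (e.g. MaxEnt output).
#' @param lexicons List with `entity_words` and `sentiment_words`.
#' @param gamma Polarity smoothing constant (>= 0).
#' @return A list of class `opinion_graph`: `nodes` (tibble `token`,
#'   `kind`, `n_pos`, `n_neg`, `polarity`), `edges` (tibble `from`, `to`,
#'   `weight`), `gamma`. Polarity is always in \eqn{[-1, 1]}.
#' @export
build_okg <- function(posts, labels, lexicons, gamma = 1) {
  node_tokens <- c(lexicons$entity_words, lexicons$sentiment_words)
  empty <- list(nodes = tibble(token = character(), kind = character(),
                               n_pos = integer(), n_neg = integer(),
                               polarity = numeric()),
                edges = tibble(from = character(), to = character(),
                               weight = numeric()),
                gamma = gamma)
  if (nrow(posts) == 0L || !length(node_tokens)) {
    return(structure(empty, class = "opinion_graph"))
  }
  stopifnot(length(labels) == nrow(posts))
  b <- corpus_dtm(posts, vocab = node_tokens)
  b@x[] <- 1  # binarize: counts are per post containing the token
  present <- Matrix::colSums(b) > 0
  b <- b[, present, drop = FALSE]
  if (ncol(b) == 0L) return(structure(empty, class = "opinion_graph"))
  n_pos <- as.integer(Matrix::colSums(b[labels == "pos", , drop = FALSE]))
  n_neg <- as.integer(Matrix::colSums(b[labels == "neg", , drop = FALSE]))
  polarity <- (n_pos - n_neg) / (n_pos + n_neg + gamma)
  polarity[n_pos + n_neg + gamma == 0] <- 0
  nodes <- tibble(token = colnames(b),
                  kind = ifelse(colnames(b) %in% lexicons$entity_words,
                                "entity", "sentiment"),
                  n_pos = n_pos, n_neg = n_neg, polarity = polarity)
  co <- Matrix::crossprod(b)
  co <- Matrix::triu(co, k = 1)
  idx <- Matrix::which(co > 0, arr.ind = TRUE)
  edges <- tibble(from = colnames(b)[idx[, 1]], to = colnames(b)[idx[, 2]],
                  weight = as.numeric(co[idx]))
  structure(list(nodes = nodes, edges = edges, gamma = gamma),
            class = "opinion_graph")
}

#' @export
print.opinion_graph <- function(x, ...) {
  cat(sprintf("<opinion_graph> %d nodes, %d edges (gamma = %g)\n",
              nrow(x$nodes), nrow(x$edges), x$gamma))
  invisible(x)
}

# One round of damped neighbor-weighted polarity averaging. Nodes without
# neighbors keep their own polarity.
okg_augmented_polarity <- function(graph, damping = 1) {
  p <- setNames(graph$nodes$polarity, graph$nodes$token)
  if (nrow(graph$edges) == 0L || damping == 0) return(p)
  e <- graph$edges
  ends <- c(e$from, e$to)
  other <- c(e$to, e$from)
  w <- rep(e$weight, 2L)
  num <- tapply(w * unname(p[other]), ends, sum)
  den <- tapply(w, ends, sum)
  nbr_mean <- p
  nbr_mean[names(num)] <- num / den
  (p + damping * nbr_mean) / (1 + damping)
}

#' Stance detection by polarity propagation on the opinion graph
#'
#' Each graph node the post touches contributes its polarity, augmented by
#' one round of damped neighbor-weighted polarity averaging. Weakly polar
#' nodes (augmented magnitude below `min_node_polarity`) contribute
#' nothing, which stops opinion-neutral entity tokens from absorbing the
#' corpus-level sentiment imbalance. The post is labeled positive if the
#' summed score exceeds `tau`, negative below `-tau`, neutral otherwise
#' (including when no node matches).
#'
#' @param graph An [build_okg()] opinion graph.
#' @param tokens Character vector of post tokens.
#' @param tau Neutral band half-width.
#' @param damping Damping of the neighbor-averaging round (0 disables it).
#' @param min_node_polarity Minimum augmented-polarity magnitude for a node
#'   to contribute.
#' @param z_gate Signal-to-noise gate: a node contributes only when its
#'   count imbalance is significant,
#'   \eqn{|n_+ - n_-| \ge z \sqrt{n_+ + n_-}}. Frequent opinion-neutral
#'   tokens are balanced and fail the gate; infrequent tokens with noisy
#'   polarity estimates fail it too; genuine opinion words pass.
#' @return A list with `stance` (`"pos"`, `"neg"` or `"neu"`) and `score`.
#' @export
propagate_stance <- function(graph, tokens, tau = 0.1, damping = 1,
                             min_node_polarity = 0.25, z_gate = 3) {
  stopifnot(inherits(graph, "opinion_graph"))
  aug <- okg_gated_polarity(graph, damping, min_node_polarity, z_gate)
  matched <- intersect(unique(tokens), names(aug))
  score <- sum(aug[matched])
  stance <- if (score > tau) "pos" else if (score < -tau) "neg" else "neu"
  list(stance = stance, score = score)
}

okg_gated_polarity <- function(graph, damping, min_node_polarity, z_gate) {
  aug <- okg_augmented_polarity(graph, damping)
  n <- graph$nodes
  significant <- abs(n$n_pos - n$n_neg) >= z_gate * sqrt(n$n_pos + n$n_neg)
  aug[!significant | abs(aug) < min_node_polarity] <- 0
  aug
}

# Vectorized stance propagation over a tokenized corpus.
okg_classify <- function(graph, posts, tau = 0.1, damping = 1,
                         min_node_polarity = 0.25, z_gate = 3) {
  if (nrow(graph$nodes) == 0L || nrow(posts) == 0L) {
    return(tibble(id = posts$id, stance = rep("neu", nrow(posts)),
                  score = rep(0, nrow(posts))))
  }
  aug <- okg_gated_polarity(graph, damping, min_node_polarity, z_gate)
  b <- corpus_dtm(posts, vocab = names(aug))
  b@x[] <- 1  # each matched node contributes once, as in propagate_stance()
  score <- as.numeric(b %*% aug)
  stance <- ifelse(score > tau, "pos", ifelse(score < -tau, "neg", "neu"))
  tibble(id = posts$id, stance = stance, score = score)
}

#' Classify an on-topic corpus: lexicon bootstrap, MaxEnt, opinion graph
#'
#' Runs the full sentiment chain: (1) bootstrap entity/sentiment lexicons
#' from POS tags and co-occurrence; (2) train the IIS maximum-entropy
#' classifier on a small stratified seed sample of expert labels (ground
#' truth in the synthetic setting); (3) label the whole corpus with the
#' MaxEnt model (training-set expansion); (4) build the opinion-aware
#' knowledge graph from the expanded labels; (5) produce the final stance
#' of every post by polarity propagation on the graph. Setting
#' `arbiter = "maxent"` skips the graph and keeps the MaxEnt labels (an
#' ablation switch).
#'
#' @param posts Tokenized on-topic post tibble with ground-truth columns
#'   (`truth_sentiment`) available for seed sampling.
#' @param n_seed_per_class Seed labels drawn per class.
#' @param f_min,c_min,window Lexicon bootstrap controls
#'   ([bootstrap_lexicon()]).
#' @param gamma Polarity smoothing of the graph.
#' @param tau,damping,min_node_polarity,z_gate Stance propagation controls
#'   ([propagate_stance()]).
#' @param tol,max_iter IIS controls ([train_maxent_iis()]).
#' @param arbiter Final label source: the opinion graph (default) or
#'   MaxEnt only.
#' @param seed Seed for the stratified seed-label draw.
#' @return The input tibble with columns `stance` and `score` appended.
#'   Attributes: `"maxent"` (the trained model), `"okg"` (the graph),
#'   `"lexicons"`, `"seed_ids"` (post ids used as expert seed labels).
#' @export
classify_corpus <- function(posts, n_seed_per_class = 200, f_min = 2, c_min = 2,
                            window = 3, gamma = 1, tau = 0.1, damping = 1,
                            min_node_polarity = 0.25, z_gate = 3, tol = 1e-6,
                            max_iter = 500, arbiter = c("okg", "maxent"),
                            seed = 1) {
  arbiter <- match.arg(arbiter)
  if (nrow(posts) == 0L) {
    out <- dplyr::mutate(posts, stance = character(0), score = numeric(0))
    return(out)
  }
  stopifnot("truth_sentiment" %in% names(posts))
  lexicons <- bootstrap_lexicon(posts, f_min = f_min, c_min = c_min,
                                window = window)
  g <- features_matrix(posts, lexicons)
  seed_ids <- with_seed(seed, {
    unlist(lapply(split(posts$id, posts$truth_sentiment), function(ids) {
      sample(ids, min(n_seed_per_class, length(ids)))
    }), use.names = FALSE)
  })
  take <- posts$id %in% seed_ids
  seed_classes <- unique(posts$truth_sentiment[take])
  if (length(seed_classes) >= 2L) {
    model <- train_maxent_iis(g[take, , drop = FALSE],
                              posts$truth_sentiment[take],
                              tol = tol, max_iter = max_iter)
    maxent_labels <- predict(model, g, type = "class")
  } else {
    # unanimous expert sample: the expansion step is degenerate and every
    # post inherits the single observed class
    model <- NULL
    maxent_labels <- rep(seed_classes, nrow(posts))
  }
  if (arbiter == "maxent") {
    score <- if (is.null(model)) {
      rep(0, nrow(posts))
    } else {
      p <- maxent_prob(g, model)
      pp <- if ("pos" %in% colnames(p)) p[, "pos"] else rep(0, nrow(p))
      pn <- if ("neg" %in% colnames(p)) p[, "neg"] else rep(0, nrow(p))
      unname(pp - pn)
    }
    res <- tibble(id = posts$id, stance = maxent_labels, score = score)
    graph <- build_okg(posts, maxent_labels, lexicons, gamma = gamma)
  } else {
    graph <- build_okg(posts, maxent_labels, lexicons, gamma = gamma)
    res <- okg_classify(graph, posts, tau = tau, damping = damping,
                        min_node_polarity = min_node_polarity, z_gate = z_gate)
  }
  out <- dplyr::left_join(posts, res, by = "id")
  for (a in c("vocab", "config")) attr(out, a) <- attr(posts, a)
  attr(out, "maxent") <- model
  attr(out, "okg") <- graph
  attr(out, "lexicons") <- lexicons
  attr(out, "seed_ids") <- seed_ids
  out
}

#' Persist lexicons and stance labels
#'
#' @param labeled Output of [classify_corpus()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_lexicons_csv <- function(labeled, path) {
  lex <- attr(labeled, "lexicons")
  graph <- attr(labeled, "okg")
  pol <- setNames(graph$nodes$polarity, graph$nodes$token)
  all_tokens <- c(lex$entity_words, lex$sentiment_words)
  df <- tibble(token = all_tokens,
               set = rep(c("entity", "sentiment"),
                         c(length(lex$entity_words), length(lex$sentiment_words))),
               polarity = unname(pol[all_tokens]))
  readr::write_csv(df, path)
  invisible(path)
}
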