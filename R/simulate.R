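# Derive an independent per-record seed from the master seed and a record
# counter, so that adding clusters never perturbs earlier records.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + as.double(k) * 1000003) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Generate a uniform random DNA sequence
#'
#' Sites are i.i.d. uniform over A, C, G, T.
#'
#' @param length Sequence length, at least 1.
#' @param seed Optional integer seed; when given the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A single uppercase DNA string.
#' @export
random_sequence <- function(length, seed = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) abort_input("length must be >= 1")
  with_seed(seed,
    paste(sample(DNA_BASES, length, replace = TRUE), collapse = ""))
}

#' Point-mutate a DNA sequence
#'
#' Each site is independently substituted with probability `sub_rate` by a
#' base drawn uniformly from the three alternatives, so a hit always changes
#' the site. Length is preserved; no indels.
#'
#' @param seq A DNA string over A, C, G, T.
#' @param sub_rate Per-site substitution probability in [0, 1].
#' @param seed Optional integer seed (see [random_sequence()]).
#' @return The mutated DNA string.
#' @export
mutate_sequence <- function(seq, sub_rate, seed = NULL) {
  if (sub_rate < 0 || sub_rate > 1) abort_input("sub_rate must be in [0, 1]")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  if (!all(chars %in% DNA_BASES)) abort_input("sequence must be over A, C, G, T")
  with_seed(seed, {
    hit <- stats::runif(length(chars)) < sub_rate
    nhit <- sum(hit)
    if (nhit > 0L) {
      cur <- match(chars[hit], DNA_BASES)
      step <- sample.int(3L, nhit, replace = TRUE)  # 1..3 skips the current base
      chars[hit] <- DNA_BASES[((cur - 1L + step) %% 4L) + 1L]
    }
    paste(chars, collapse = "")
  })
}

#' Simulate clustered sequence families
#'
#' Draws `n_clusters` independent random ancestors and, for each, `per_cluster`
#' descendants obtained by point mutation at rate `sub_rate`. The returned
#' dataset holds the descendants, labeled by their cluster; the ancestors are
#' kept in the `ancestors` attribute. Each record's sequence is driven by its
#' own seed derived from `seed` and the record's position, so the output is
#' bit-reproducible and adding clusters leaves earlier clusters unchanged.
#'
#' @param n_clusters Number of independent ancestral sequences.
#' @param per_cluster Descendants simulated per ancestor.
#' @param length Sequence length in nucleotides.
#' @param sub_rate Per-site substitution probability ancestor -> descendant.
#' @param seed Master integer seed.
#' @return A labeled [pcnv_dataset] of `n_clusters * per_cluster` records
#'   with ids like `cluster1_seq01`, plus attribute `ancestors`.
#' @export
make_clusters <- function(n_clusters = 4L, per_cluster = 10L, length = 5000L,
                          sub_rate = 0.01, seed = 1L) {
  if (n_clusters < 1L || per_cluster < 1L) abort_input("counts must be >= 1")
  width <- max(2L, nchar(as.character(per_cluster)))
  records <- character(0L)
  ancestors <- character(n_clusters)
  k <- 0L
  for (ci in seq_len(n_clusters)) {
    k <- k + 1L
    anc <- random_sequence(length, seed = derive_seed(seed, k))
    ancestors[ci] <- anc
    for (di in seq_len(per_cluster)) {
      k <- k + 1L
      id <- sprintf("cluster%d_seq%0*d", ci, width, di)
      records[id] <- mutate_sequence(anc, sub_rate, seed = derive_seed(seed, k))
    }
  }
  labels <- stats::setNames(
    rep(paste0("cluster", seq_len(n_clusters)), each = per_cluster),
    names(records))
  ds <- pcnv_dataset(records, labels)
  attr(ds, "ancestors") <- stats::setNames(
    ancestors, paste0("cluster", seq_len(n_clusters)))
  ds
}
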