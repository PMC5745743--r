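#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more query hits in a pathway of size
#' `K` when `n` query proteins are drawn without replacement from a
#' background of `N_bg`: `P(X >= k)` for
#' `X ~ Hypergeometric(N_bg, K, n)`. The sum is accumulated in log
#' space for numerical stability.
#'
#' @param k observed overlap (>= 0).
#' @param K pathway size within the background.
#' @param n query size.
#' @param N_bg background (universe) size.
#' @return a probability in (0, 1]; exactly 1 when `k <= 0`.
#' @export
hypergeometric_tail <- function(k, K, n, N_bg) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N_bg) == 1)
  k <- as.numeric(k); K <- as.numeric(K); n <- as.numeric(n); N_bg <- as.numeric(N_bg)
  if (K < 0 || n < 0 || N_bg < 1) stop("counts must be nonnegative with N_bg >= 1")
  if (K > N_bg || n > N_bg) stop("K and n cannot exceed N_bg")
  if (k > min(K, n)) stop("k cannot exceed min(K, n)")
  if (k <= 0) return(1)
  j <- seq(k, min(K, n))
  lt <- lchoose(K, j) + lchoose(N_bg - K, n - j) - lchoose(N_bg, n)
  m <- max(lt)
  p <- exp(m + log(sum(exp(lt - m))))
  min(1, max(p, 0))
}

#' Pathway over-representation analysis
#'
#' Tests each pathway for over-representation of the query protein set
#' using the one-sided hypergeometric upper tail, the standard
#' over-representation statistic for pathway annotation. Pathway
#' members are intersected with the background before testing; pathways
#' with no member in the background are skipped. Significance is called
#' on the raw p-value by default (`p < alpha`); with
#' `correction = "benjamini_hochberg"` it is called on the BH-adjusted
#' p-value instead.
#'
#' @param query character vector of protein ids (must lie within the
#'   background).
#' @param pathways a [pathway_collection()].
#' @param background universe of protein ids; default is the union of
#'   all pathway members and the query.
#' @param alpha significance threshold, default 0.01.
#' @param correction `"none"` (default) or `"benjamini_hochberg"`.
#' @return data frame sorted by ascending p-value with columns
#'   `pathway_id`, `description`, `overlap`, `pathway_size`,
#'   `query_size`, `background_size`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
enrich_pathways <- function(query, pathways, background = NULL, alpha = 0.01,
                            correction = c("none", "benjamini_hochberg")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pathways, "pathway_collection"))
  query <- unique(as.character(query))
  if (is.null(background)) {
    background <- union(unlist(pathways$sets, use.names = FALSE), query)
  }
  background <- unique(as.character(background))
  if (length(background) == 0L) stop("background universe is empty")
  if (!all(query %in% background)) stop("query contains ids outside the background")
  n <- length(query)
  N_bg <- length(background)
  rows <- lapply(names(pathways$sets), function(id) {
    members <- intersect(pathways$sets[[id]], background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, query))
    data.frame(pathway_id = id,
               description = unname(pathways$descriptions[[id]]),
               overlap = k, pathway_size = K, query_size = n,
               background_size = N_bg,
               p_value = hypergeometric_tail(k, K, n, N_bg),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(pathway_id = character(), description = character(),
                      overlap = integer(), pathway_size = integer(),
                      query_size = integer(), background_size = integer(),
                      p_value = numeric(), p_adjusted = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
    return(res)
  }
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- if (correction == "none") res$p_value < alpha
                     else res$p_adjusted < alpha
  res <- res[order(res$p_value, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
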