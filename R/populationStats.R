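## Cell-type-level statistics of the innervation matrix: convergence,
## divergence, population connection probability and the averaged
## synapse-count distribution.
##
## All ensemble averages treat absent matrix entries as I = 0 (no overlap).
## Autapse entries (the same neuron appearing as pre and post) are excluded
## by default; the flag reverses this.

.pairProbs <- function(im, A, B) {
  pre <- rownames(im@matrix); post <- colnames(im@matrix)
  if (!all(A %in% pre)) stop("unknown presynaptic ids", call. = FALSE)
  if (!all(B %in% post)) stop("unknown postsynaptic ids", call. = FALSE)
  sub <- as.matrix(im@matrix[match(A, pre), match(B, post), drop = FALSE])
  connectionProbability(sub)
}

#' Convergence onto a postsynaptic neuron
#'
#' The expected fraction of the presynaptic population \code{A} connected to
#' the single postsynaptic neuron \code{b}: the mean over \code{a} in A of
#' \code{p_ab = 1 - exp(-I_ab)}.
#'
#' @param im an [InnervationMatrix-class]
#' @param A character vector of presynaptic neuron ids (nonempty).
#' @param b a single postsynaptic neuron id.
#' @param excludeAutapses drop \code{a == b} from the average (default TRUE).
#' @return probability in [0, 1].
#' @export
convergence <- function(im, A, b, excludeAutapses = TRUE) {
  stopifnot(length(b) == 1L)
  if (excludeAutapses) A <- setdiff(A, b)
  if (!length(A)) stop("empty presynaptic population", call. = FALSE)
  mean(.pairProbs(im, A, b))
}

#' Divergence of a presynaptic neuron
#'
#' The expected fraction of the postsynaptic population \code{B} targeted by
#' the single presynaptic neuron \code{a}.
#'
#' @param im an [InnervationMatrix-class]
#' @param a a single presynaptic neuron id.
#' @param B character vector of postsynaptic neuron ids (nonempty).
#' @param excludeAutapses drop \code{b == a} (default TRUE).
#' @return probability in [0, 1].
#' @export
divergence <- function(im, a, B, excludeAutapses = TRUE) {
  stopifnot(length(a) == 1L)
  if (excludeAutapses) B <- setdiff(B, a)
  if (!length(B)) stop("empty postsynaptic population", call. = FALSE)
  mean(.pairProbs(im, a, B))
}

#' Population-level connectivity summary
#'
#' For presynaptic population A and postsynaptic population B computes: the
#' population connection probability \code{P_AB} (grand mean of p_ab), the
#' per-post-neuron convergence with its mean and SD across B, the
#' per-pre-neuron divergence, and the averaged synapse-count distribution
#' \code{n_AB} (the mean of the per-pair Poisson mass functions). The reported
#' synapse range is \code{[1, q]} with q the smallest count whose cumulative
#' conditional probability (given at least one synapse) reaches
#' \code{rangeLevel}.
#'
#' @param im an [InnervationMatrix-class]
#' @param A,B character vectors of pre-/postsynaptic neuron ids.
#' @param excludeAutapses drop a == b pairs from all averages (default TRUE).
#' @param rangeLevel cumulative level of the synapse range (default 0.99).
#' @return list with elements \code{P_AB}, \code{convergence} (named vector
#'   over B), \code{convergenceMean}, \code{convergenceSD}, \code{divergence}
#'   (named vector over A), \code{nAB} (data.frame n, p),
#'   \code{meanSynapses} (mean I over pairs), \code{synapseRange}
#'   (integer(2)), \code{nPre}, \code{nPost}.
#' @export
populationSummary <- function(im, A, B, excludeAutapses = TRUE,
                              rangeLevel = 0.99) {
  if (!length(A) || !length(B)) stop("empty selections", call. = FALSE)
  p <- .pairProbs(im, A, B)
  Isub <- as.matrix(im@matrix[match(A, rownames(im@matrix)),
                              match(B, colnames(im@matrix)), drop = FALSE])
  keep <- matrix(TRUE, length(A), length(B))
  if (excludeAutapses) {
    both <- intersect(A, B)
    for (x in both) keep[match(x, A), match(x, B)] <- FALSE
  }
  if (!any(keep)) stop("no pairs left after autapse exclusion", call. = FALSE)
  P_AB <- mean(p[keep])
  conv <- vapply(seq_along(B), function(jx) {
    k <- keep[, jx]
    if (!any(k)) NA_real_ else mean(p[k, jx])
  }, numeric(1))
  names(conv) <- B
  div <- vapply(seq_along(A), function(ix) {
    k <- keep[ix, ]
    if (!any(k)) NA_real_ else mean(p[ix, k])
  }, numeric(1))
  names(div) <- A
  Ivals <- Isub[keep]
  nMax <- max(1L, max(vapply(Ivals, function(I) qpois(1 - 1e-9, I),
                             numeric(1))))
  n <- 0:nMax
  pmf <- rowMeans(vapply(Ivals, function(I) dpois(n, I), numeric(length(n))))
  cond <- pmf[-1L] / sum(pmf[-1L])
  q <- if (all(!is.finite(cond))) NA_integer_
       else which(cumsum(cond) >= rangeLevel)[1L]
  list(P_AB = P_AB,
       convergence = conv,
       convergenceMean = mean(conv, na.rm = TRUE),
       convergenceSD = stats::sd(conv, na.rm = TRUE),
       divergence = div,
       nAB = data.frame(n = n, p = pmf),
       meanSynapses = mean(Ivals),
       synapseRange = c(1L, as.integer(q)),
       nPre = length(A), nPost = length(B))
}

#' Write a population summary report as CSV
#'
#' One row per (pre type, post type, column) combination present in the
#' matrix annotations, with P_AB, convergence mean and SD, the synapse range
#' and population sizes.
#'
#' @param im an [InnervationMatrix-class]
#' @param path output path.
#' @param excludeAutapses passed to [populationSummary].
#' @return the report data.frame, invisibly; written to \code{path}.
#' @export
writePopulationReport <- function(im, path, excludeAutapses = TRUE) {
  combos <- expand.grid(
    pre_type = unique(im@preInfo$cell_type),
    post_type = unique(im@postInfo$cell_type),
    column = unique(im@postInfo$column),
    stringsAsFactors = FALSE)
  rows <- list()
  for (r in seq_len(nrow(combos))) {
    A <- im@preInfo$id[im@preInfo$cell_type == combos$pre_type[r]]
    B <- im@postInfo$id[im@postInfo$cell_type == combos$post_type[r] &
                        im@postInfo$column == combos$column[r]]
    if (!length(A) || !length(B)) next
    s <- populationSummary(im, A, B, excludeAutapses = excludeAutapses)
    rows[[length(rows) + 1L]] <- data.frame(
      pre_type = combos$pre_type[r], post_type = combos$post_type[r],
      column = combos$column[r], P_AB = s$P_AB,
      convergence_mean = s$convergenceMean, convergence_sd = s$convergenceSD,
      syn_min = s$synapseRange[1L], syn_max = s$synapseRange[2L],
      n_pre = s$nPre, n_post = s$nPost, stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, rows)
  write.csv(rep, path, row.names = FALSE, quote = FALSE)
  invisible(rep)
}
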