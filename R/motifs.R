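## Directed triplet-motif analysis.
##
## Three neurons are joined by six possible directed edges, in fixed order
## (1,2),(2,1),(1,3),(3,1),(2,3),(3,2); the 64 on/off configurations reduce
## to 16 classes under the 6 node permutations (S3 isomorphism). Classes are
## numbered by edge count (number of connected node pairs) descending, ties
## broken by the lexicographically smallest member configuration, so the
## 7 three-connected classes come first and the empty motif is class 16.

.EDGE_PAIRS <- matrix(c(1L, 2L, 2L, 1L, 1L, 3L, 3L, 1L, 2L, 3L, 3L, 2L),
                      ncol = 2L, byrow = TRUE)

# 0..63 -> logical(6) edge state and back (bit 1 = first edge)
.configBits <- function(code) as.logical(bitwAnd(code, 2L^(0:5)) > 0)
.bitsCode <- function(bits) as.integer(sum(2L^(0:5) * as.integer(bits)))

# apply node permutation sigma (integer(3)) to a configuration code:
# edge (a,b) of the permuted configuration is on iff edge (sigma[a], sigma[b])
# is on in the original.
.permuteConfig <- function(code, sigma) {
  bits <- .configBits(code)
  mapped <- vapply(seq_len(6L), function(e) {
    a <- sigma[.EDGE_PAIRS[e, 1L]]
    b <- sigma[.EDGE_PAIRS[e, 2L]]
    which(.EDGE_PAIRS[, 1L] == a & .EDGE_PAIRS[, 2L] == b)
  }, integer(1))
  .bitsCode(bits[mapped])
}

.S3_PERMS <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

.motifEnv <- new.env(parent = emptyenv())

#' Enumerate the 16 triplet motif classes
#'
#' Partitions the 64 directed-edge configurations into isomorphism classes
#' under the 6 node permutations, by exhaustive orbit enumeration. The
#' partition has 16 classes: 7 with three connected node pairs, 6 with two,
#' 2 with one, and 1 with none.
#'
#' @return list with \code{classes} (data.frame: \code{motif_id},
#'   \code{edge_count} = connected node pairs, \code{n_members},
#'   \code{representative} = smallest member code 0..63) and
#'   \code{classOf} (integer(64): motif class of each configuration code
#'   0..63, position \code{c + 1}).
#' @export
motifClasses <- function() {
  hit <- .motifEnv$classes
  if (!is.null(hit)) return(hit)
  codes <- 0:63
  orbit <- rep(NA_integer_, 64L)  # orbit representative (minimum code)
  for (c in codes) {
    imgs <- vapply(.S3_PERMS, function(s) .permuteConfig(c, s), integer(1))
    orbit[c + 1L] <- min(imgs)
  }
  # connected node pairs per configuration
  pairCount <- vapply(codes, function(c) {
    b <- .configBits(c)
    sum(b[1L] | b[2L], b[3L] | b[4L], b[5L] | b[6L])
  }, integer(1))
  reps <- sort(unique(orbit))
  repEdges <- pairCount[reps + 1L]
  ord <- order(-repEdges, reps)
  reps <- reps[ord]
  classes <- data.frame(
    motif_id = seq_along(reps),
    edge_count = pairCount[reps + 1L],
    n_members = vapply(reps, function(r) sum(orbit == r), integer(1)),
    representative = reps)
  classOf <- match(orbit, reps)
  out <- list(classes = classes, classOf = classOf)
  .motifEnv$classes <- out
  out
}

#' Motif spectrum of one neuron triplet
#'
#' Given the six directed-edge probabilities in the order
#' p12, p21, p13, p31, p23, p32, computes each configuration's probability as
#' the product over the six edges of \code{p_e} (edge present) or
#' \code{1 - p_e} (edge absent), and sums members within each motif class.
#'
#' @param p numeric(6) of edge probabilities in [0, 1].
#' @return data.frame \code{motif_id, edge_count, n_members, probability};
#'   probabilities sum to 1.
#' @export
tripletSpectrum <- function(p) {
  if (length(p) != 6L || any(p < 0 | p > 1) || any(!is.finite(p)))
    stop("p must be six probabilities in [0, 1]", call. = FALSE)
  mc <- motifClasses()
  probs <- vapply(0:63, function(c) {
    b <- .configBits(c)
    prod(ifelse(b, p, 1 - p))
  }, numeric(1))
  agg <- rowsum(probs, mc$classOf)
  out <- mc$classes[, c("motif_id", "edge_count", "n_members")]
  out$probability <- as.numeric(agg[match(out$motif_id,
                                          as.integer(rownames(agg)))])
  out
}

# six edge probabilities of an id triplet from an innervation matrix, in the
# order p12, p21, p13, p31, p23, p32
.tripletEdgeProbs <- function(im, ids) {
  stopifnot(length(ids) == 3L)
  ri <- match(ids, rownames(im@matrix))
  ci <- match(ids, colnames(im@matrix))
  if (any(is.na(ri)) || any(is.na(ci)))
    stop("triplet ids must appear on both matrix axes", call. = FALSE)
  I <- vapply(seq_len(6L), function(e)
    im@matrix[ri[.EDGE_PAIRS[e, 1L]], ci[.EDGE_PAIRS[e, 2L]]], numeric(1))
  connectionProbability(I)
}

#' Motif spectrum of a specific neuron triplet in a matrix
#' @param im an [InnervationMatrix-class] whose axes share the neuron ids.
#' @param ids three neuron ids.
#' @return as [tripletSpectrum]
#' @export
tripletSpectrumFromMatrix <- function(im, ids) {
  tripletSpectrum(.tripletEdgeProbs(im, ids))
}

# Sample nTriplets index triplets from n neurons such that no two triplets
# share more than one neuron (no neuron pair is reused). Rejection sampling.
.sampleTriplets <- function(n, nTriplets, seed, maxAttempts = 200L * nTriplets) {
  maxFeasible <- floor(choose(n, 2) / 3)
  if (n < 3L || (nTriplets > 1L && nTriplets > maxFeasible))
    stop(sprintf(paste0("cannot draw %d triplets with pairwise overlap <= 1 ",
                        "from %d neurons; at most %d are feasible"),
                 nTriplets, n, max(1, maxFeasible)), call. = FALSE)
  withSeed(seed, {
    used <- new.env(parent = emptyenv(), size = 4L * nTriplets)
    out <- matrix(NA_integer_, nTriplets, 3L)
    got <- 0L
    attempts <- 0L
    while (got < nTriplets) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop(sprintf(paste0("triplet sampling stalled after %d attempts; ",
                            "at most ~%d triplets are feasible for %d neurons"),
                     attempts, max(1, maxFeasible), n), call. = FALSE)
      tri <- sort(sample.int(n, 3L))
      keys <- c(paste(tri[1L], tri[2L]), paste(tri[1L], tri[3L]),
                paste(tri[2L], tri[3L]))
      if (any(vapply(keys, function(k) !is.null(used[[k]]), logical(1))))
        next
      for (k in keys) used[[k]] <- TRUE
      got <- got + 1L
      out[got, ] <- tri
    }
    out
  })
}

#' Population motif spectrum by triplet sampling
#'
#' Repeats \code{nRepeats} times: draw \code{nTriplets} neuron triplets
#' uniformly at random, subject to any two triplets sharing at most one
#' neuron, compute each triplet's motif spectrum from the pairwise connection
#' probabilities, and average within the repeat. Reports mean and SD across
#' repeats per motif class.
#'
#' @param im an [InnervationMatrix-class] with identical pre/post id sets for
#'   the population.
#' @param ids neuron ids of the population (>= 3).
#' @param nTriplets triplets per repeat (default 2000).
#' @param nRepeats number of repeats (default 10).
#' @param seed integer seed.
#' @return data.frame \code{motif_id, edge_count, n_members, prob_mean,
#'   prob_sd}.
#' @export
populationSpectrum <- function(im, ids, nTriplets = 2000L, nRepeats = 10L,
                               seed = 1L) {
  n <- length(ids)
  if (n < 3L) stop("population must contain at least 3 neurons", call. = FALSE)
  if (n == 3L) nTriplets <- 1L
  mc <- motifClasses()
  spectra <- matrix(NA_real_, nRepeats, 16L)
  for (rep_ in seq_len(nRepeats)) {
    tri <- .sampleTriplets(n, nTriplets, childSeed(seed, 7L, rep_))
    acc <- numeric(16L)
    for (r in seq_len(nrow(tri))) {
      sp <- tripletSpectrumFromMatrix(im, ids[tri[r, ]])
      acc <- acc + sp$probability
    }
    spectra[rep_, ] <- acc / nrow(tri)
  }
  data.frame(motif_id = mc$classes$motif_id,
             edge_count = mc$classes$edge_count,
             n_members = mc$classes$n_members,
             prob_mean = colMeans(spectra),
             prob_sd = apply(spectra, 2L, stats::sd))
}

#' Compare a motif spectrum against a uniform-connectivity null
#'
#' The null spectrum assumes every directed edge has the same probability
#' \code{pUniform} (a homogeneous random network with the population's mean
#' pairwise connection probability). Reports the relative deviation
#' \code{(observed - null) / null} and a z-score using the across-repeat SD
#' of the observed spectrum (the null is deterministic).
#'
#' @param spectrum output of [populationSpectrum] (needs \code{prob_mean} and
#'   \code{prob_sd}).
#' @param pUniform the uniform edge probability in [0, 1].
#' @return data.frame \code{motif_id, edge_count, prob_mean, prob_sd,
#'   null_prob, deviation, z}. Classes with a zero null and nonzero observed
#'   probability get infinite deviation (flagged by a warning).
#' @export
uniformNullComparison <- function(spectrum, pUniform) {
  if (pUniform < 0 || pUniform > 1)
    stop("pUniform must be in [0, 1]", call. = FALSE)
  null <- tripletSpectrum(rep(pUniform, 6L))
  obs <- spectrum$prob_mean
  sdv <- spectrum$prob_sd %||% rep(0, length(obs))
  dev <- (obs - null$probability) / null$probability
  if (any(null$probability == 0 & obs > 0)) {
    warning("observed probability in class(es) with zero null probability",
            call. = FALSE)
    dev[null$probability == 0 & obs > 0] <- Inf
  }
  dev[null$probability == 0 & obs == 0] <- 0
  z <- ifelse(sdv > 0, (obs - null$probability) / sdv,
              ifelse(obs == null$probability, 0, Inf * sign(obs - null$probability)))
  data.frame(motif_id = spectrum$motif_id, edge_count = spectrum$edge_count,
             prob_mean = obs, prob_sd = sdv, null_prob = null$probability,
             deviation = dev, z = z)
}

#' Write a motif report as CSV
#'
#' Columns \code{motif_id,edge_count,n_members,prob_mean,prob_sd,null_prob,}
#' \code{deviation,z}.
#' @param spectrum output of [populationSpectrum].
#' @param pUniform uniform edge probability of the null.
#' @param path output path.
#' @return the report, invisibly.
#' @export
writeMotifReport <- function(spectrum, pUniform, path) {
  cmp <- uniformNullComparison(spectrum, pUniform)
  cmp$n_members <- spectrum$n_members
  cmp <- cmp[, c("motif_id", "edge_count", "n_members", "prob_mean",
                 "prob_sd", "null_prob", "deviation", "z")]
  write.csv(cmp, path, row.names = FALSE, quote = FALSE)
  invisible(cmp)
}
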