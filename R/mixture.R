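## The EM engine: responsibilities, parameter updates, fitting with
## restarts, likelihood-based selection of k, and hard assignment.
##
## All likelihood arithmetic is in log space (per-position log sums,
## log-sum-exp across components) so datasets of 1e5 seeds never underflow.

## N x k component log-likelihood matrix via one matrix product on the
## one-hot encoding. log(0) entries are clamped for the product and then
## restored to the -Inf sentinel: legitimate per-seed log-likelihoods never
## go below about -5e3, so the threshold is unambiguous.
.componentLogLik <- function(oh, pwms) {
  lw <- .logPwmMatrix(pwms)
  lw[!is.finite(lw)] <- -1e10
  ll <- oh %*% t(lw)
  ll[ll < -1e9] <- -Inf
  ll
}

.posterior <- function(ll, lambdas) {
  lp <- sweep(ll, 2L, log(lambdas), "+")
  lse <- .logSumExpRows(lp)
  if (any(!is.finite(lse)))
    stop("some sequence has zero likelihood under every component; ",
         "use a pseudocount > 0")
  list(z = exp(lp - lse), marg = sum(lse))
}

#' E-step: posterior component responsibilities
#'
#' Computes z_mi = lambda_i P(X_m | W_i) / sum_j lambda_j P(X_m | W_j) via
#' log-sum-exp; every row sums to 1.
#'
#' @param seedSet a \linkS4class{SeedSet}.
#' @param model a \linkS4class{PWMixture}.
#' @return numeric N x k row-stochastic matrix with row names = record ids.
#' @export
eStep <- function(seedSet, model) {
  oh <- .oneHot(.encodeSeeds(seedSet))
  z <- .posterior(.componentLogLik(oh, model@pwms), model@lambdas)$z
  rownames(z) <- seqIds(seedSet)
  z
}

#' Marginal log-likelihood of a seed set under a mixture
#'
#' sum_m log sum_i lambda_i P(X_m | W_i), the objective the EM iterations
#' ascend.
#'
#' @inheritParams eStep
#' @return scalar log-likelihood (natural log).
#' @export
marginalLogLik <- function(seedSet, model) {
  oh <- .oneHot(.encodeSeeds(seedSet))
  lp <- sweep(.componentLogLik(oh, model@pwms), 2L, log(model@lambdas), "+")
  lse <- .logSumExpRows(lp)
  if (any(!is.finite(lse)))
    stop("some sequence has zero likelihood under every component; ",
         "use a pseudocount > 0")
  sum(lse)
}

## Shared M-step core on precomputed one-hot data.
.mStepCore <- function(oh, z, L, pseudocount, variant, pwms = NULL) {
  n <- nrow(z); k <- ncol(z)
  lambdas <- colSums(z) / n
  counts <- crossprod(oh, z)                       # 4L x k weighted counts
  newPwms <- vector("list", k)
  for (i in seq_len(k)) {
    C <- matrix(counts[, i], 4L, L)
    if (variant == "literal") {
      if (is.null(pwms))
        stop("the literal update needs the current PWMs")
      C <- pwms[[i]]@probs * C
    }
    C <- C + pseudocount
    cs <- colSums(C)
    if (any(cs == 0)) {
      warning("component ", i, " has zero total responsibility and no ",
              "pseudocount; its PWM is left unchanged")
      newPwms[[i]] <- if (!is.null(pwms)) pwms[[i]] else PWM(matrix(0.25, 4, L))
    } else {
      newPwms[[i]] <- PWM(sweep(C, 2L, cs, "/"))
    }
  }
  list(lambdas = lambdas, pwms = newPwms)
}

#' M-step: maximum-likelihood parameter updates
#'
#' Mixing weights are always the responsibility column means,
#' lambda_i = (1/N) sum_m z_mi. The \code{"standard"} PWM update uses
#' pseudocount-smoothed responsibility-weighted base counts,
#' W_i[b,v] = (c + sum_m 1\{X_mv = b\} z_mi) / (4c + sum_m z_mi); this is
#' the maximizer of the expected complete-data log-likelihood and
#' guarantees likelihood ascent. The \code{"literal"} variant additionally
#' weights each count by the current matrix entry and renormalizes per
#' column; it is retained for fidelity experiments and does not guarantee
#' ascent (see the methods vignette).
#'
#' @param seedSet a \linkS4class{SeedSet}.
#' @param responsibilities N x k row-stochastic matrix.
#' @param pseudocount non-negative smoothing constant added per cell.
#' @param variant \code{"standard"} (default) or \code{"literal"}.
#' @param pwms current list of PWMs; required for \code{"literal"} and used
#'   as the fallback for a component with zero total responsibility.
#' @return list with elements \code{lambdas} and \code{pwms}.
#' @export
mStep <- function(seedSet, responsibilities, pseudocount = 1e-4,
                  variant = c("standard", "literal"), pwms = NULL) {
  variant <- match.arg(variant)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  enc <- .encodeSeeds(seedSet)
  if (nrow(enc) != nrow(responsibilities))
    stop("responsibilities must have one row per seed record")
  .mStepCore(.oneHot(enc), responsibilities, ncol(enc), pseudocount,
             variant, pwms)
}

#' Fit a PWM mixture by expectation-maximization
#'
#' Alternates E- and M-steps from a seeded initialization (uniform mixing
#' weights, PWMs from \code{\link{initPWMs}}) until the relative change in
#' marginal log-likelihood drops below \code{tol} or \code{maxIter} is
#' reached. Fully deterministic given \code{rngSeed}. With the standard
#' M-step the recorded trajectory is non-decreasing.
#'
#' @param seedSet a \linkS4class{SeedSet} (N >= 1 records).
#' @param k number of mixture components (>= 1).
#' @param initMode \code{"from_sequences"} or \code{"dirichlet"}, see
#'   \code{\link{initPWMs}}.
#' @param pseudocount per-cell smoothing in the M-step (default 1e-4; 0 is
#'   allowed but zero-probability entries then surface as errors when a
#'   sequence has zero likelihood under every component).
#' @param tol relative log-likelihood convergence threshold.
#' @param maxIter maximum number of EM iterations.
#' @param rngSeed integer seed for the initialization.
#' @param matchWeight initialization match weight, see \code{\link{initPWMs}}.
#' @param mStepVariant \code{"standard"} or \code{"literal"}.
#' @param background optional background sequences for initialization.
#' @param initPwms optional explicit list of k starting PWMs (overrides
#'   \code{initMode}).
#' @return a fitted \linkS4class{PWMixture} carrying the final
#'   responsibility matrix and the log-likelihood trajectory.
#' @examples
#' set.seed(1)
#' ss <- SeedSet(paste0("s", 1:20),
#'               sample(c("AAAAAA", "CCCCCC"), 20, replace = TRUE))
#' fit <- fitMixture(ss, k = 2, rngSeed = 7)
#' mixingWeights(fit)
#' @export
fitMixture <- function(seedSet, k, initMode = c("from_sequences", "dirichlet"),
                       pseudocount = 1e-4, tol = 1e-8, maxIter = 500L,
                       rngSeed = 1L, matchWeight = 0.7,
                       mStepVariant = c("standard", "literal"),
                       background = NULL, initPwms = NULL) {
  initMode <- match.arg(initMode)
  mStepVariant <- match.arg(mStepVariant)
  if (k < 1) stop("k must be >= 1")
  if (length(seedSet) < 1) stop("need at least one seed record")
  enc <- .encodeSeeds(seedSet)
  L <- ncol(enc)
  oh <- .oneHot(enc)
  pwms <- if (!is.null(initPwms)) initPwms
          else initPWMs(seedSet, k, mode = initMode,
                        matchWeight = matchWeight, rngSeed = rngSeed,
                        background = background)
  lambdas <- rep(1 / k, k)
  traj <- numeric(0)
  prev <- NA_real_
  converged <- FALSE
  z <- NULL
  for (iter in seq_len(maxIter)) {
    post <- .posterior(.componentLogLik(oh, pwms), lambdas)
    z <- post$z
    traj[iter] <- post$marg
    if (iter > 1L && abs(post$marg - prev) < tol * abs(prev)) {
      converged <- TRUE
      break
    }
    prev <- post$marg
    upd <- .mStepCore(oh, z, L, pseudocount, mStepVariant, pwms)
    lambdas <- upd$lambdas
    pwms <- upd$pwms
  }
  rownames(z) <- seqIds(seedSet)
  new("PWMixture", k = as.integer(k), lambdas = lambdas, pwms = pwms,
      responsibilities = z, loglikTrajectory = traj,
      rngSeed = as.integer(rngSeed), converged = converged,
      nIter = length(traj))
}

## Restart seeds derived deterministically from the master seed so a scan
## is reproducible end to end; kept below 2^31.
.deriveSeed <- function(master, k, restart) {
  as.integer((as.numeric(master) * 1009 + as.numeric(k) * 101 +
                as.numeric(restart)) %% (.Machine$integer.max - 1L) + 1L)
}

#' Scan the number of clusters with restarted fits
#'
#' For each k runs \code{restarts} independent EM fits from distinct seeds
#' derived from the master seed, keeps the maximum-likelihood fit per k,
#' and returns the overall maximum-likelihood model together with the full
#' (k, best restart, best log-likelihood) table. No complexity penalty is
#' applied across k; the raw table lets the user inspect the k-vs-likelihood
#' shape.
#'
#' @param seedSet a \linkS4class{SeedSet}.
#' @param kValues integer vector of component counts to try.
#' @param restarts number of random restarts per k (>= 1).
#' @param rngSeed master seed; restart seeds are derived from it.
#' @param ... further arguments passed to \code{\link{fitMixture}}.
#' @return list with elements \code{model} (the overall best
#'   \linkS4class{PWMixture}), \code{bestK}, and \code{table} (data.frame
#'   with columns k, best_restart, best_loglik).
#' @export
scanK <- function(seedSet, kValues, restarts = 10L, rngSeed = 1L, ...) {
  if (length(kValues) == 0) stop("kValues must be non-empty")
  if (restarts < 1) stop("restarts must be >= 1")
  best <- NULL
  bestLL <- -Inf
  tab <- data.frame(k = integer(), best_restart = integer(),
                    best_loglik = numeric())
  for (k in kValues) {
    kBest <- NULL
    kBestLL <- -Inf
    kBestR <- NA_integer_
    for (r in seq_len(restarts)) {
      fit <- fitMixture(seedSet, k,
                        rngSeed = .deriveSeed(rngSeed, k, r), ...)
      ll <- utils::tail(fit@loglikTrajectory, 1L)
      if (ll > kBestLL) {
        kBest <- fit; kBestLL <- ll; kBestR <- r
      }
    }
    tab <- rbind(tab, data.frame(k = as.integer(k), best_restart = kBestR,
                                 best_loglik = kBestLL))
    if (kBestLL > bestLL) {
      best <- kBest; bestLL <- kBestLL
    }
  }
  list(model = best, bestK = best@k, table = tab)
}

#' @rdname assignGroups
#' @export
setMethod("assignGroups", "matrix", function(x) {
  if (nrow(x) == 0)
    return(Grouping(stats::setNames(integer(), character()), k = ncol(x)))
  labels <- max.col(x, ties.method = "first")
  Grouping(stats::setNames(labels, rownames(x)), k = ncol(x))
})

#' @rdname assignGroups
#' @export
setMethod("assignGroups", "PWMixture", function(x) {
  assignGroups(x@responsibilities)
})

#' Write a fitted mixture model to JSON
#'
#' Fields: schema_version, L, k, base_order (A, C, G, U), lambdas, pwms
#' (k x 4 x L nested arrays, rows in base order), rng_seed, n_iter,
#' converged, final_loglik. Numbers are written at full precision so a
#' read/write round trip is bit-stable.
#'
#' @param model a \linkS4class{PWMixture}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMixtureModel <- function(model, path) {
  obj <- list(
    schema_version = 1L,
    L = seedWidth(model),
    k = model@k,
    base_order = as.list(.BASES),
    lambdas = model@lambdas,
    pwms = lapply(model@pwms, function(p) unname(p@probs)),
    rng_seed = model@rngSeed,
    n_iter = model@nIter,
    converged = model@converged,
    final_loglik = if (length(model@loglikTrajectory))
      utils::tail(model@loglikTrajectory, 1L) else NA_real_)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a mixture model from JSON
#'
#' Inverse of \code{\link{writeMixtureModel}}; the responsibility matrix is
#' not part of the model file (it lives in the assignments TSV).
#'
#' @param path path to a model JSON file.
#' @return a \linkS4class{PWMixture}.
#' @export
readMixtureModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(unlist(obj$base_order), c("A", "C", "G", "U")))
    stop("unexpected base_order in model file: ", path)
  pwms <- if (is.array(obj$pwms) && length(dim(obj$pwms)) == 3L) {
    lapply(seq_len(dim(obj$pwms)[1]), function(i) PWM(obj$pwms[i, , ]))
  } else {
    lapply(obj$pwms, function(p) PWM(do.call(rbind, p)))
  }
  new("PWMixture", k = as.integer(obj$k), lambdas = as.numeric(obj$lambdas),
      pwms = pwms, responsibilities = matrix(numeric(), 0, obj$k),
      loglikTrajectory = as.numeric(obj$final_loglik),
      rngSeed = as.integer(obj$rng_seed), converged = as.logical(obj$converged),
      nIter = as.integer(obj$n_iter))
}
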