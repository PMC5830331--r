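## Mutational signatures: synthetic reference set, per-sample refitting by
## iterative signature addition (deconstructSigs convention), and de novo
## extraction by stability-selected NMF with KL multiplicative updates.

#' Deterministic synthetic reference signature matrix
#'
#' Builds a 96 x K matrix of synthetic mutational signatures (columns sum
#' to 1). The shapes emulate processes discussed for esophageal tissue --
#' `SS1` peaks at C>T in NpCpG context (clock-like deamination of
#' 5-methylcytosine), `SS17` at T>G and T>C in NTT context (the signature
#' enriched in esophageal adenocarcinoma), `SS2` at TpC (APOBEC-like), `SS4`
#' broad C>A (tobacco-like) -- plus less structured fillers. The set is
#' synthetic: it is NOT the COSMIC catalog, and columns are named `SS*` to
#' make that explicit.
#'
#' @param k Number of signatures (2..10).
#' @return 96 x k matrix, rownames the channel labels.
#' @export
make_reference_signatures <- function(k = 10L) {
  chans <- channel_order()
  sub_of <- sub("^.\\[(.*)\\].$", "\\1", chans)
  five <- substr(chans, 1, 1)
  three <- substr(chans, 7, 7)

  peak <- function(sub, f = NULL, t = NULL) {
    w <- sub_of == sub
    if (!is.null(f)) w <- w & five %in% f
    if (!is.null(t)) w <- w & three %in% t
    as.numeric(w)
  }
  norm1 <- function(x) x / sum(x)
  mix <- function(..., bg = 0.08) {
    parts <- list(...)
    v <- rep(bg / 96, 96)
    for (p in parts) v <- v + (1 - bg) * p$w * norm1(p$shape)
    norm1(v)
  }
  part <- function(shape, w) list(shape = shape, w = w)

  sigs <- list(
    SS1 = mix(part(peak("C>T", t = "G"), 0.75), part(peak("C>T"), 0.25)),
    SS17 = mix(part(peak("T>G", t = "T"), 0.55),
               part(peak("T>C", t = "T"), 0.30),
               part(peak("T>G"), 0.15)),
    SS2 = mix(part(peak("C>T", f = "T"), 0.55), part(peak("C>G", f = "T"), 0.45)),
    SS4 = mix(part(peak("C>A"), 0.70), part(peak("C>A", f = c("C", "T")), 0.30)),
    SS5 = mix(part(peak("T>C"), 0.45), part(peak("C>T"), 0.35),
              part(peak("C>A"), 0.20), bg = 0.30),
    SS8 = mix(part(peak("C>A", t = c("A", "T")), 0.60),
              part(peak("T>A"), 0.40)),
    SS9 = mix(part(peak("T>G", f = c("A", "G")), 0.40),
              part(peak("T>C", f = "A"), 0.40), part(peak("C>G"), 0.20)),
    SS18 = mix(part(peak("C>A", f = "G"), 0.70), part(peak("C>A", t = "A"), 0.30)),
    SS3 = mix(bg = 1),
    SS6 = mix(part(peak("C>T", f = "G", t = c("C", "A")), 0.60),
              part(peak("T>A", f = "C"), 0.40))
  )
  k <- as.integer(k)
  stopifnot(k >= 2L, k <= length(sigs))
  m <- do.call(cbind, sigs[seq_len(k)])
  rownames(m) <- chans
  m
}

#' Cosine similarity of two non-negative spectra
#'
#' @param u,v Numeric vectors of equal length; neither all-zero.
#' @return `u . v / (|u| |v|)`, in `[0, 1]` for non-negative input.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector")
  sum(u * v) / (nu * nv)
}

## Lawson-Hanson non-negative least squares: minimize |A x - b|^2, x >= 0.
nnls_fit <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- rep(0, n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- rep(0, n)
      s[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(s[passive] > tol)) break
      qs <- which(passive & s <= tol)
      alpha <- min(x[qs] / (x[qs] - s[qs]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

#' Refit a sample spectrum against reference signatures
#'
#' Finds the non-negative mixture of reference signatures that best fits the
#' normalized 96-channel spectrum, by iterative single-signature addition with
#' full re-optimization (non-negative least squares) at each step, and discard
#' of signatures whose weight falls below `weight_floor` (the deconstructSigs
#' convention). Samples with fewer than `min_snv` SNVs are considered too
#' sparse to refit: all assigned counts are zero and `below_min_flag` is set.
#'
#' @param patient_spectrum Integer 96-vector of channel counts.
#' @param reference 96 x R matrix of reference signatures, columns summing
#'   to 1.
#' @param min_snv Minimum number of SNVs required to attempt a refit.
#' @param weight_floor Discard threshold on normalized weights.
#' @param tol Stop adding signatures when the squared-error improvement drops
#'   below this value.
#' @return List with `weights` (named, >= 0, summing to <= 1),
#'   `assigned_counts` (weights x SNV total), `residual` (root squared error
#'   of the normalized fit) and `below_min_flag`.
#' @export
refit_weights <- function(patient_spectrum, reference, min_snv = 50L,
                          weight_floor = 0.06, tol = 1e-4) {
  stopifnot(length(patient_spectrum) == nrow(reference))
  colsums <- colSums(reference)
  stopifnot(all(abs(colsums - 1) < 1e-6))
  total <- sum(patient_spectrum)
  zero <- list(
    weights = stats::setNames(rep(0, ncol(reference)), colnames(reference)),
    assigned_counts = stats::setNames(rep(0, ncol(reference)),
                                      colnames(reference)),
    residual = NA_real_, below_min_flag = TRUE
  )
  if (total < min_snv) return(zero)

  b <- patient_spectrum / total
  active <- integer(0)
  sse <- sum(b^2)
  repeat {
    cand <- setdiff(seq_len(ncol(reference)), active)
    if (length(cand) == 0L) break
    best <- NULL
    for (j in cand) {
      idx <- c(active, j)
      x <- nnls_fit(reference[, idx, drop = FALSE], b)
      r <- b - reference[, idx, drop = FALSE] %*% x
      s <- sum(r^2)
      if (is.null(best) || s < best$sse) best <- list(j = j, sse = s, x = x)
    }
    if (sse - best$sse < tol) break
    active <- c(active, best$j)
    sse <- best$sse
  }
  w <- rep(0, ncol(reference))
  if (length(active)) {
    x <- nnls_fit(reference[, active, drop = FALSE], b)
    # discard sub-threshold contributions, then refit the survivors
    repeat {
      frac <- if (sum(x) > 0) x / sum(x) else x
      drop_idx <- which(x > 0 & frac < weight_floor)
      if (length(drop_idx) == 0L) break
      active <- active[-drop_idx]
      if (length(active) == 0L) { x <- numeric(0); break }
      x <- nnls_fit(reference[, active, drop = FALSE], b)
    }
    w[active] <- x
  }
  # mixture interpretation: weights sum to at most 1, remainder is residual
  if (sum(w) > 1) w <- w / sum(w)
  fitted <- as.numeric(reference %*% w)
  names(w) <- colnames(reference)
  list(
    weights = w,
    assigned_counts = w * total,
    residual = sqrt(sum((b - fitted)^2)),
    below_min_flag = FALSE
  )
}

#' Refit every patient of a spectrum matrix
#'
#' @param spectrum Patients x 96 matrix from [build_spectrum].
#' @param reference Reference signature matrix.
#' @param ... Passed to [refit_weights].
#' @return List with `weights` and `assigned_counts` (patients x R matrices),
#'   `below_min` (logical vector), `residual`.
#' @export
refit_cohort <- function(spectrum, reference, ...) {
  fits <- apply(spectrum, 1L, refit_weights, reference = reference, ...,
                simplify = FALSE)
  list(
    weights = do.call(rbind, lapply(fits, `[[`, "weights")),
    assigned_counts = do.call(rbind, lapply(fits, `[[`, "assigned_counts")),
    below_min = vapply(fits, `[[`, logical(1), "below_min_flag"),
    residual = vapply(fits, `[[`, numeric(1), "residual")
  )
}

## One KL-NMF fit with multiplicative updates. V: 96 x n, k: rank.
.nmf_kl <- function(V, k, max_iter = 400L, tol = 1e-6) {
  eps <- 1e-12
  m <- nrow(V); n <- ncol(V)
  W <- matrix(stats::runif(m * k, 0.1, 1), m, k)
  H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  W <- sweep(W, 2L, colSums(W), "/")
  scale <- mean(colSums(V))
  H <- H * scale / mean(colSums(H))
  div_old <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / (matrix(rowSums(H), m, k, byrow = TRUE) + eps)
    WH <- W %*% H + eps
    H <- H * (t(W) %*% (V / WH)) / (matrix(colSums(W), k, n) + eps)
    if (it %% 20L == 0L) {
      WH <- W %*% H + eps
      div <- sum(V * log((V + eps) / WH) - V + WH)
      if (is.finite(div_old) && abs(div_old - div) < tol * (abs(div) + 1)) break
      div_old <- div
    }
  }
  # fix scaling: signatures are probability vectors
  cs <- colSums(W)
  W <- sweep(W, 2L, cs, "/")
  H <- H * cs
  WH <- W %*% H + eps
  div <- sum(V * log((V + eps) / WH) - V + WH)
  list(W = W, H = H, divergence = div)
}

## mean silhouette of a clustering under cosine distance
.mean_silhouette <- function(X, cl) {
  k <- length(unique(cl))
  if (k < 2L) return(1)
  n <- nrow(X)
  Xn <- X / sqrt(rowSums(X^2))
  D <- 1 - tcrossprod(Xn)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(cl == cl[i]); same <- setdiff(same, i)
    a <- if (length(same)) mean(D[i, same]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(D[i, cl == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' De novo signature extraction by stability-selected NMF
#'
#' For each candidate rank k, each patient's spectrum is bootstrap-perturbed
#' (multinomial resampling of its channel counts) `n_resamples` times; each
#' perturbed matrix is factorized by KL-divergence NMF with multiplicative
#' updates (`n_restarts` random restarts, best divergence kept). The pooled
#' signature vectors are clustered into k groups by hierarchical clustering on
#' cosine distance, and per-rank stability is the mean silhouette of that
#' clustering. The selected rank maximizes mean silhouette among ranks with
#' silhouette >= `min_stability` (falling back to the overall maximum when no
#' rank qualifies). Final signatures are the normalized cluster centroids;
#' exposures are per-patient non-negative least-squares fits of the original
#' counts.
#'
#' @param spectrum Patients x 96 count matrix.
#' @param k_range Candidate ranks.
#' @param n_resamples Bootstrap resamples per rank.
#' @param seed RNG seed (local to this call).
#' @param n_restarts Random restarts per factorization.
#' @param min_stability Silhouette threshold for rank selection.
#' @return List with `W` (96 x k), `H` (k x patients), `k`, `stability`
#'   (per-rank mean silhouette), `reconstruction_error` (Frobenius, on
#'   counts).
#' @export
extract_signatures_nmf <- function(spectrum, k_range = 1:4,
                                   n_resamples = 8L, seed = 1L,
                                   n_restarts = 10L, min_stability = 0.8) {
  stopifnot(nrow(spectrum) >= 2L)
  if (sum(spectrum) < 96) stop("too few SNVs for signature extraction")
  if (max(k_range) > min(96L, nrow(spectrum))) {
    stop("k_range exceeds min(96, number of patients)")
  }
  V <- t(spectrum) # 96 x patients
  withr::with_seed(seed, {
    per_k <- lapply(k_range, function(k) {
      sigs <- vector("list", n_resamples)
      for (r in seq_len(n_resamples)) {
        Vr <- apply(V, 2L, function(v) {
          tot <- sum(v)
          if (tot == 0) v else as.numeric(stats::rmultinom(1L, tot, v / tot))
        })
        best <- NULL
        for (s in seq_len(n_restarts)) {
          fit <- .nmf_kl(Vr, k)
          if (is.null(best) || fit$divergence < best$divergence) best <- fit
        }
        sigs[[r]] <- best$W
      }
      S <- t(do.call(cbind, sigs)) # (k * n_resamples) x 96
      if (k == 1L) {
        cl <- rep(1L, nrow(S))
      } else {
        Sn <- S / sqrt(rowSums(S^2))
        d <- stats::as.dist(1 - tcrossprod(Sn))
        cl <- stats::cutree(stats::hclust(d, method = "average"), k = k)
      }
      centroids <- t(vapply(seq_len(k), function(g) {
        colMeans(S[cl == g, , drop = FALSE])
      }, numeric(96L)))
      centroids <- centroids / rowSums(centroids)
      list(k = k, silhouette = .mean_silhouette(S, cl),
           W = t(centroids)) # 96 x k
    })
    sil <- vapply(per_k, `[[`, numeric(1), "silhouette")
    # the single-cluster silhouette is 1 by convention, so k = 1 must not
    # compete on silhouette: select the most stable multi-signature rank,
    # falling back to rank 1 when no k >= 2 clustering is stable
    multi <- which(k_range >= 2L & sil >= min_stability)
    pick <- if (length(multi)) {
      multi[which.max(sil[multi])]
    } else if (1L %in% k_range) {
      which(k_range == 1L)
    } else {
      which.max(sil)
    }
    W <- per_k[[pick]]$W
    H <- vapply(seq_len(ncol(V)), function(i) nnls_fit(W, V[, i]),
                numeric(ncol(W)))
    H <- matrix(H, nrow = ncol(W),
                dimnames = list(paste0("N", seq_len(ncol(W))),
                                rownames(spectrum)))
    rownames(W) <- colnames(spectrum)
    colnames(W) <- rownames(H)
    list(W = W, H = H, k = k_range[pick],
         stability = stats::setNames(sil, paste0("k", k_range)),
         reconstruction_error = sqrt(sum((V - W %*% H)^2)))
  })
}

#' Regression of per-signature mutation loads on covariates
#'
#' For each signature, fits `log(assigned count + 1)` on the given covariate
#' set via [multivariable_lm]. `covariates` may name columns of `meta` or the
#' composite contrast `"never_smoker_user"` (never-smoker NSAID users vs all
#' other participants).
#'
#' @param assigned_counts Patients x signatures matrix of mutation counts.
#' @param meta Patient table.
#' @param covariates Character vector of covariate names.
#' @return data.frame with one row per (signature, term).
#' @export
signature_load_regression <- function(assigned_counts, meta,
                                      covariates = "nsaid_user") {
  stopifnot(nrow(assigned_counts) == nrow(meta), all(assigned_counts >= 0))
  design <- lapply(covariates, function(cv) {
    if (cv == "never_smoker_user") {
      meta$nsaid_user & !meta$ever_smoker
    } else if (cv %in% names(meta)) {
      meta[[cv]]
    } else {
      stop("unknown covariate: ", cv)
    }
  })
  names(design) <- covariates
  design <- as.data.frame(design)
  out <- lapply(colnames(assigned_counts), function(sig) {
    tab <- multivariable_lm(assigned_counts[, sig], design)
    tab$signature <- sig
    tab
  })
  res <- do.call(rbind, out)
  res[c("signature", setdiff(names(res), "signature"))]
}
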