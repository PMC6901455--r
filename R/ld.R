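#' Genotypic LD between two SNPs
#'
#' Composite (unphased) linkage disequilibrium: the squared Pearson
#' correlation of allele dosages over samples with complete calls at both
#' SNPs. Symmetric and in [0, 1]. When either SNP is monomorphic over the
#' shared complete cases, LD is undefined and `NA` is returned (distinct
#' from 0).
#'
#' @param g a [geno_matrix()].
#' @param snp_a,snp_b SNP ids or column indices.
#' @return Squared correlation, or `NA_real_` when undefined.
#' @export
ld_r2 <- function(g, snp_a, snp_b) {
  stopifnot(inherits(g, "geno_matrix"))
  idx <- function(s) {
    j <- if (is.character(s)) match(s, g$snps$snp_id) else as.integer(s)
    if (is.na(j) || j < 1 || j > nrow(g$snps)) stop("unknown SNP: ", s)
    j
  }
  a <- g$dosage[, idx(snp_a)]
  b <- g$dosage[, idx(snp_b)]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

# r^2 of one dosage column against a block of columns; NA where undefined
.r2_vec <- function(x, M) {
  apply(M, 2, function(y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2) return(NA_real_)
    xs <- x[ok]; ys <- y[ok]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)^2
  })
}

#' Sliding-window LD pruning
#'
#' Greedy pruning in the PLINK idiom: within each window of `window_size`
#' SNPs (slid by `step`), pairs of retained SNPs with squared dosage
#' correlation above `r2_threshold` are resolved by dropping the
#' later-positioned SNP. Deterministic for a fixed input. Monomorphic pairs
#' (undefined LD) are never treated as correlated.
#'
#' @param g a [geno_matrix()]; SNPs are processed in column order, which
#'   should be genomic order.
#' @param r2_threshold squared-correlation cutoff in (0, 1); default 0.25,
#'   the conventional value for pruning ahead of ancestry PCA.
#' @param window_size SNPs per window (>= 2).
#' @param step SNPs to slide between windows (>= 1).
#' @return Character vector of retained SNP ids, in input order.
#' @export
ld_prune <- function(g, r2_threshold = 0.25, window_size = 50, step = 5) {
  stopifnot(inherits(g, "geno_matrix"))
  if (r2_threshold <= 0 || r2_threshold >= 1)
    stop("r2_threshold must lie in (0, 1)")
  if (window_size < 2) stop("window_size must be >= 2")
  if (step < 1) stop("step must be >= 1")
  p <- nrow(g$snps)
  keep <- rep(TRUE, p)
  start <- 1L
  repeat {
    end <- min(start + window_size - 1L, p)
    win <- which(keep[start:end]) + start - 1L
    if (length(win) > 1) {
      for (ii in seq_along(win)[-length(win)]) {
        i <- win[ii]
        if (!keep[i]) next
        later <- win[win > i & keep[win]]
        if (!length(later)) next
        r2 <- .r2_vec(g$dosage[, i], g$dosage[, later, drop = FALSE])
        drop <- later[!is.na(r2) & r2 > r2_threshold]
        keep[drop] <- FALSE
      }
    }
    if (end >= p) break
    start <- start + step
  }
  g$snps$snp_id[keep]
}

#' Ancestry principal components from pruned genotypes
#'
#' Computes the top-k principal components of the standardized dosage
#' matrix: missing dosages are mean-imputed, then each SNP is centered at
#' twice its sample allele frequency and scaled by sqrt(2 p (1 - p)), the
#' binomial standard deviation under Hardy-Weinberg equilibrium. Components
#' are ordered by decreasing explained variance; the sign of each component
#' is fixed so that its first nonzero SNP loading is positive.
#'
#' @param g a [geno_matrix()].
#' @param pruned_ids SNP ids to use (typically from [ld_prune()]); default
#'   all SNPs.
#' @param k number of components (>= 1).
#' @return Numeric matrix (samples x k) with columns `PC1..PCk`, rows named
#'   by sample ID; each column has zero mean. Attribute `"sdev"` carries the
#'   singular values / sqrt(n - 1).
#' @export
compute_pcs <- function(g, pruned_ids = NULL, k = 2) {
  stopifnot(inherits(g, "geno_matrix"), k >= 1)
  if (is.null(pruned_ids)) pruned_ids <- g$snps$snp_id
  if (!length(pruned_ids)) stop("pruned_ids is empty")
  idx <- match(pruned_ids, g$snps$snp_id)
  if (anyNA(idx))
    stop("unknown SNP ids: ", paste(pruned_ids[is.na(idx)], collapse = ", "))
  D <- g$dosage[, idx, drop = FALSE]
  storage.mode(D) <- "double"
  p_hat <- colMeans(D, na.rm = TRUE) / 2
  poly <- p_hat > 0 & p_hat < 1 & !is.na(p_hat)
  if (!any(poly))
    stop("no polymorphic SNPs: genotype matrix has zero variance")
  D <- D[, poly, drop = FALSE]
  p_hat <- p_hat[poly]
  for (j in seq_len(ncol(D))) {
    miss <- is.na(D[, j])
    if (any(miss)) D[miss, j] <- 2 * p_hat[j]
  }
  Z <- sweep(D, 2, 2 * p_hat)
  Z <- sweep(Z, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  sv <- svd(Z, nu = min(dim(Z)), nv = 0)
  tol <- max(dim(Z)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  if (k > rank)
    stop("k = ", k, " exceeds the rank (", rank, ") of the genotype matrix")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  # sign convention: first sample with a nonzero score... fixed via loadings:
  # flip so the first nonzero loading of each PC is positive
  V <- crossprod(Z, sv$u[, seq_len(k), drop = FALSE])
  for (j in seq_len(k)) {
    nz <- which(abs(V[, j]) > 1e-12)
    if (length(nz) && V[nz[1], j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(g$samples, paste0("PC", seq_len(k)))
  structure(scores, sdev = sv$d[seq_len(k)] / sqrt(nrow(Z) - 1))
}
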