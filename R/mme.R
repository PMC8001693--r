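# Model frame, Henderson mixed-model equations and direct BLUP solve for the
# random regression model
#   y = Xb + Hq + Za + Wp + e
# with Legendre-polynomial age covariates for the fixed year-season-of-birth
# regressions and for the herd-year-season (q), additive-genetic (a) and
# permanent-environment (p) random regressions.

#' Prior specification for the random regression model
#'
#' Fixed effects get a vague zero-mean normal prior with a large common
#' variance. The three coefficient covariance matrices follow inverted
#' Wishart priors `IW(df, V)` (density proportional to
#' `|S|^-(df+k+1)/2 exp(-tr(V S^-1)/2)`), with small identity scale matrices
#' by default; with the default `df = 3` and `k = 5` the prior is improper
#' (flagged, harmless once data enter the posterior). The residual variance
#' follows a scaled inverted chi-squared prior.
#'
#' @param k number of Legendre coefficients per random effect.
#' @param sigma_b fixed-effect prior variance (default `1e10`).
#' @param iw_df inverted Wishart degrees of freedom (default 3).
#' @param V_g,V_q,V_p inverted Wishart scale matrices (default `0.01 I_k`).
#' @param resid_df,resid_scale scaled inverted chi-squared parameters for the
#'   residual variance (defaults 3 and 0.1).
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(k = 5, sigma_b = 1e10, iw_df = 3,
                       V_g = diag(0.01, k), V_q = diag(0.01, k),
                       V_p = diag(0.01, k),
                       resid_df = 3, resid_scale = 0.1) {
  for (V in list(V_g, V_q, V_p))
    if (!is_psd(V) || nrow(V) != k) stop("IW scale matrices must be k x k PSD")
  structure(list(k = as.integer(k), sigma_b = sigma_b, iw_df = iw_df,
                 V_g = V_g, V_q = V_q, V_p = V_p,
                 resid_df = resid_df, resid_scale = resid_scale,
                 improper = iw_df <= k - 1),
            class = "prior_spec")
}

#' Variance components on the coefficient scale
#'
#' @param G0,Rq,Rp k x k symmetric PSD covariance matrices of the additive,
#'   herd-year-season and permanent-environment regression coefficients.
#' @param sigma_e2 residual variance (> 0).
#' @return object of class `variance_components`.
#' @export
variance_components <- function(G0, Rq, Rp, sigma_e2) {
  for (nm in c("G0", "Rq", "Rp")) {
    M <- get(nm)
    if (!is_psd(M)) stop(nm, " must be symmetric PSD")
  }
  if (sigma_e2 <= 0) stop("sigma_e2 must be > 0")
  structure(list(G0 = G0, Rq = Rq, Rp = Rp, sigma_e2 = sigma_e2),
            class = "variance_components")
}

#' Assemble the model frame for a trait
#'
#' Joins the non-missing trait records with cow metadata and the pedigree
#' into the index structure shared by the direct solver and the Gibbs
#' sampler: record-level age covariates, year-season-of-birth fixed
#' regression classes, the embryo-transfer covariate, herd-year-season
#' classes, animal positions in the (full) pedigree, and
#' permanent-environment levels.
#'
#' @param records `trajectory_records` from [code_trajectories()]; missing
#'   codes are dropped here.
#' @param histories the `cow_histories` the records were coded from.
#' @param pedigree the full pedigree (EBVs are predicted for every animal).
#' @param basis a [legendre_basis()].
#' @return object of class `rrm_data`.
#' @export
rrm_data <- function(records, histories, pedigree, basis = legendre_basis()) {
  rec <- records[!is.na(records$code), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no non-missing records")
  hrow <- match(rec$cow, histories$cow)
  if (anyNA(hrow)) stop("records refer to cows absent from histories")
  age_idx <- match(rec$age, basis$ages)

  ys <- factor(paste(histories$birth_year[hrow], histories$birth_season[hrow],
                     sep = "-"))
  hys <- factor(hys_key(histories$herd[hrow],
                        histories$birth_year[hrow] + rec$age,
                        histories$birth_season[hrow]))
  anim <- match(rec$cow, pedigree$id)
  if (anyNA(anim)) stop("records refer to animals absent from the pedigree")
  pe <- factor(rec$cow, levels = unique(rec$cow))

  structure(list(
    y = as.numeric(rec$code),
    age_idx = as.integer(age_idx),
    Phi = basis$T,
    ys = as.integer(ys), ys_levels = levels(ys),
    et = as.numeric(histories$et_flag[hrow]),
    hys = as.integer(hys), hys_levels = levels(hys),
    anim = as.integer(anim), animal_ids = pedigree$id,
    pe = as.integer(pe), pe_levels = levels(pe),
    basis = basis, cow = rec$cow, age = rec$age,
    trait = attr(records, "trait")),
    class = "rrm_data")
}

#' @export
print.rrm_data <- function(x, ...) {
  cat("RRM model frame:", length(x$y), "records,",
      length(unique(x$cow)), "cows,", length(x$animal_ids), "animals,",
      length(x$hys_levels), "HYS classes, k =", x$basis$k, "\n")
  invisible(x)
}

# Sparse record-by-coefficient design for one levelled Legendre regression.
level_design <- function(level, n_levels, phi_rows) {
  k <- ncol(phi_rows)
  n <- length(level)
  Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k),
    j = as.vector(t((level - 1L) * k + matrix(seq_len(k), n, k, byrow = TRUE))),
    x = as.vector(t(phi_rows)),
    dims = c(n, n_levels * k))
}

# Full sparse design [X | H | Z | W] and the column blocks.
rrm_design <- function(data) {
  k <- data$basis$k
  phi <- data$Phi[data$age_idx, , drop = FALSE]
  X_ys <- level_design(data$ys, length(data$ys_levels), phi)
  X_et <- Matrix::Matrix(data$et, ncol = 1, sparse = TRUE)
  H <- level_design(data$hys, length(data$hys_levels), phi)
  Z <- level_design(data$anim, length(data$animal_ids), phi)
  W <- level_design(data$pe, length(data$pe_levels), phi)
  blocks <- list(ys = ncol(X_ys), et = 1L, hys = ncol(H), anim = ncol(Z),
                 pe = ncol(W))
  list(M = cbind(X_ys, X_et, H, Z, W), blocks = blocks, k = k)
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the sparse coefficient matrix and right-hand side
#' `C s = r` with `C = M' M / sigma_e2 + D`, where `D` carries the
#' fixed-effect ridge `I / sigma_b` and the random-effect precisions
#' `Rq^-1 (x) I`, `G0^-1 (x) A^-1` and `Rp^-1 (x) I`.
#'
#' @param data an [rrm_data()] model frame.
#' @param vc [variance_components()] to condition on.
#' @param priors a [prior_spec()] (supplies the fixed-effect ridge).
#' @param ainv optional precomputed `A^-1` for the animals in `data`.
#' @return list with `C` (sparse symmetric), `rhs`, `blocks`, `sigma_e2`.
#' @export
assemble_mme <- function(data, vc, priors = prior_spec(k = data$basis$k),
                         ainv = NULL) {
  des <- rrm_design(data)
  k <- des$k
  if (is.null(ainv))
    stop("assemble_mme needs the pedigree A-inverse (build_ainverse)")
  nb <- des$blocks
  D <- Matrix::bdiag(
    Matrix::Diagonal(nb$ys + nb$et, 1 / priors$sigma_b),
    Matrix::Diagonal(nb$hys / k) %x% solve(vc$Rq),
    ainv %x% solve(vc$G0),
    Matrix::Diagonal(nb$pe / k) %x% solve(vc$Rp))
  C <- Matrix::crossprod(des$M) / vc$sigma_e2 + D
  rhs <- Matrix::crossprod(des$M, data$y) / vc$sigma_e2
  ch <- try(Matrix::Cholesky(Matrix::forceSymmetric(C), LDL = FALSE,
                             perm = TRUE), silent = TRUE)
  if (inherits(ch, "try-error"))
    stop("mixed-model equations are singular after ridge stabilization")
  list(C = C, rhs = rhs, chol = ch, blocks = des$blocks, k = k,
       sigma_e2 = vc$sigma_e2, M = des$M, y = data$y, data = data)
}

split_solution <- function(sol, blocks, k, data) {
  off <- 0L
  out <- list()
  for (nm in names(blocks)) {
    v <- sol[off + seq_len(blocks[[nm]])]
    off <- off + blocks[[nm]]
    out[[nm]] <- if (nm == "et") as.numeric(v) else
      matrix(v, ncol = k, byrow = TRUE)
  }
  rownames(out$ys) <- data$ys_levels
  rownames(out$hys) <- data$hys_levels
  rownames(out$anim) <- data$animal_ids
  rownames(out$pe) <- data$pe_levels
  out
}

#' Solve the mixed-model equations (BLUP)
#'
#' Direct sparse Cholesky solve; the relative residual norm of the linear
#' system is reported so convergence is verifiable.
#'
#' @param system output of [assemble_mme()].
#' @return list of solutions `ys` (fixed regressions), `et`, `hys`, `anim`,
#'   `pe` (each a levels x k matrix, except the scalar `et`), plus
#'   `residual_norm`.
#' @export
solve_blup <- function(system) {
  sol <- as.numeric(Matrix::solve(system$chol, system$rhs))
  res <- as.numeric(system$C %*% sol - system$rhs)
  rn <- sqrt(sum(res^2)) / max(1e-300, sqrt(sum(system$rhs^2)))
  if (!is.finite(rn) || rn > 1e-6)
    stop("BLUP solve did not converge: relative residual ", format(rn))
  out <- split_solution(sol, system$blocks, system$k, system$data)
  out$residual_norm <- rn
  out$solution <- sol
  out
}
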