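#' Marginal log-likelihood by nested Gauss-Hermite quadrature
#'
#' Evaluates the exact marginal log-likelihood of the logistic survival
#' model at a given parameter point by numerical integration instead of the
#' Laplace approximation: the plant-level integral is solved by
#' Gauss-Hermite quadrature inside a Gauss-Hermite integral over the site
#' effect (plants must be nested within sites, as in the monitoring
#' design). Useful as an independent accuracy check on
#' \code{\link{fit_survival_glmm}}'s Laplace log-likelihood on small
#' problems.
#'
#' @param records Monitoring data.frame (as for
#'   \code{\link{fit_survival_glmm}}).
#' @param fixed A \code{\link{survival_fixed_effects}} set.
#' @param random A \code{\link{survival_random_effects}} set.
#' @param nodes Number of quadrature nodes per dimension.
#' @return The marginal log-likelihood (a single number).
#' @export
survival_loglik_gh <- function(records, fixed, random, nodes = 15) {
  gh <- gauss_hermite(nodes)
  ## probabilist's normalisation: b = sqrt(2) * sd * x, weights / sqrt(pi)
  w <- gh$weights / sqrt(pi)
  x <- gh$nodes * sqrt(2)
  sp <- sqrt(random$var_plant)
  ss <- sqrt(random$var_site)

  eta0 <- fixed$intercept + fixed$contrasts[as.character(records$treatment)] +
    fixed$age_slope * records$age
  y <- as.numeric(records$alive)

  ## check nesting
  tab <- unique(records[, c("plant_id", "site_id")])
  if (anyDuplicated(tab$plant_id))
    stop("plants must be nested within sites for the quadrature evaluator",
         call. = FALSE)

  ll <- 0
  for (s in unique(records$site_id)) {
    rs <- records$site_id == s
    ## site-level integral
    site_lik <- vapply(seq_along(x), function(j) {
      us <- ss * x[j]
      lik_site <- 1
      for (p in unique(records$plant_id[rs])) {
        rp <- rs & records$plant_id == p
        e <- eta0[rp] + us
        ## plant-level integral
        lp <- vapply(seq_along(x), function(k) {
          pr <- stats::plogis(e + sp * x[k])
          prod(ifelse(y[rp] == 1, pr, 1 - pr))
        }, numeric(1))
        lik_site <- lik_site * sum(w * lp)
      }
      lik_site
    }, numeric(1))
    ll <- ll + log(sum(w * site_lik))
  }
  as.numeric(ll)
}

## Gauss-Hermite nodes/weights via the Golub-Welsch eigen decomposition of
## the Jacobi matrix (physicists' convention: weight exp(-x^2)).
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx],
       weights = sqrt(pi) * e$vectors[1, idx]^2)
}
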