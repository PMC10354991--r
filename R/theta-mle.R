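# Maximum-likelihood correction of shear-site (fragment-length) counts.
#
# Sonication breaks DNA at near-random positions, so the number of DISTINCT
# fragment lengths observed at an integration site tracks the number of
# progenitor cells carrying it -- but saturates as independent progenitors
# collide on the same length. Model: the number of fragments of length l
# produced at site i is Poisson(theta_i * phi_l), with theta_i the
# progenitor abundance and phi a length distribution shared across sites;
# only presence y_il = 1{count > 0} is observed, i.e.
# y_il ~ Bernoulli(1 - exp(-theta_i * phi_l)).
# The fit alternates an exact per-site maximization of theta (monotone 1-D
# root finding on the score) with an EM-style update of phi from the
# expected fragment counts given presence -- a hybrid EM.

#' Estimate per-site progenitor abundance from fragment lengths
#'
#' @param profiles A list of integer vectors, one per site, each the
#'   observed fragment lengths at that site (duplicates are collapsed to
#'   presence). List names become site ids.
#' @param phi Optional fixed length distribution summing to 1. Names, when
#'   present, are the fragment lengths; an unnamed vector is treated as L
#'   anonymous length bins with the pooled observed lengths assigned to the
#'   leading bins in sorted order. When supplied, only theta is estimated --
#'   with a single site and uniform `phi` over `L` lengths the estimate
#'   equals the closed form `-L * log(1 - d/L)` for `d` observed lengths.
#' @param max_iter Maximum alternation sweeps (default 500).
#' @param tol Relative convergence tolerance on theta and phi (default 1e-8).
#' @param theta_cap Cap for saturated sites (a site observed at every pooled
#'   length has a divergent MLE; it is capped and flagged unconverged).
#' @return An object of class `theta_fit`: use [tidy()] for per-site
#'   estimates (`site_id`, `d`, `theta`, `converged`), [glance()] for fit
#'   summary, `$phi` for the length distribution.
#' @examples
#' fit <- estimate_theta_mle(list(s1 = c(200, 340, 510)),
#'                           phi = rep(1 / 200, 200))
#' tidy(fit)$theta # ~ -200 * log(1 - 3/200)
#' @export
estimate_theta_mle <- function(profiles, phi = NULL, max_iter = 500L,
                               tol = 1e-8, theta_cap = 1e6) {
  stopifnot(length(profiles) >= 1)
  site_ids <- names(profiles) %||% paste0("site_", seq_along(profiles))
  profiles <- lapply(profiles, unique)

  if (is.null(phi)) {
    lengths_pool <- sort(unique(unlist(profiles)))
    if (length(lengths_pool) < 2) {
      stop("need at least 2 distinct fragment lengths across profiles ",
           "to estimate phi; supply a fixed phi instead", call. = FALSE)
    }
    phi_vec <- rep(1 / length(lengths_pool), length(lengths_pool))
    fixed_phi <- FALSE
  } else {
    stopifnot(all(phi >= 0), abs(sum(phi) - 1) < 1e-6)
    if (!is.null(names(phi))) {
      lengths_pool <- as.numeric(names(phi))
    } else {
      # unnamed phi: L anonymous length bins; pooled observed lengths are
      # assigned to the leading bins in sorted order
      observed <- sort(unique(unlist(profiles)))
      if (length(observed) > length(phi)) {
        stop("phi has fewer bins than there are distinct observed lengths",
             call. = FALSE)
      }
      lengths_pool <- c(observed,
                        rep(NA_real_, length(phi) - length(observed)))
    }
    phi_vec <- as.numeric(phi)
    fixed_phi <- TRUE
  }

  L <- length(lengths_pool)
  Y <- matrix(0L, nrow = length(profiles), ncol = L)
  for (i in seq_along(profiles)) {
    Y[i, match(intersect(profiles[[i]], lengths_pool), lengths_pool)] <- 1L
  }
  d <- rowSums(Y)
  theta <- pmax(d, 0.5)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    theta_new <- vapply(seq_len(nrow(Y)), function(i) {
      solve_theta(Y[i, ], phi_vec, cap = theta_cap)
    }, numeric(1))
    if (fixed_phi) {
      delta <- max(abs(theta_new - theta) / pmax(theta, 1e-12))
      theta <- theta_new
      if (delta < tol || iter >= max_iter) {
        converged <- delta < tol
        break
      }
      next
    }
    # EM update of phi: expected fragment count at (i, l) given presence
    tp <- outer(theta_new, phi_vec)
    w <- Y * ifelse(tp > 0, tp / (1 - exp(-tp)), 0)
    w[Y == 1 & tp == 0] <- 1  # presence with phi = 0: minimal mass
    phi_new <- colSums(w)
    phi_new <- phi_new / sum(phi_new)
    delta <- max(abs(theta_new - theta) / pmax(theta, 1e-12),
                 abs(phi_new - phi_vec))
    theta <- theta_new
    phi_vec <- phi_new
    if (delta < tol || iter >= max_iter) {
      converged <- delta < tol
      break
    }
  }

  capped <- theta >= theta_cap
  est <- new_tbl(
    site_id = site_ids,
    d = as.integer(d),
    theta = theta,
    converged = converged & !capped
  )
  ll <- theta_loglik(Y, theta, phi_vec)
  structure(
    list(
      estimates = est,
      phi = new_tbl(fragment_len = lengths_pool, phi = phi_vec),
      iterations = iter,
      converged = converged && !any(capped),
      loglik = ll,
      fixed_phi = fixed_phi
    ),
    class = "theta_fit"
  )
}

# Root of the per-site score
#   sum_{l: y=1} phi_l / (exp(theta phi_l) - 1) - sum_{l: y=0} phi_l = 0,
# strictly decreasing in theta; diverges when no zero-cell has phi mass.
solve_theta <- function(y, phi, cap) {
  on <- y == 1 & phi > 0
  off_mass <- sum(phi[y == 0])
  if (!any(on)) return(0)
  if (off_mass <= 0) return(cap)  # saturated: MLE diverges
  score <- function(th) {
    e <- exp(th * phi[on])
    sum(phi[on] / (e - 1)) - off_mass
  }
  lo <- sum(on) / 2
  while (score(lo) < 0 && lo > 1e-12) lo <- lo / 4
  hi <- max(2 * sum(on), 1)
  while (score(hi) > 0) {
    hi <- hi * 4
    if (hi >= cap) return(cap)
  }
  stats::uniroot(score, c(lo, hi), tol = 1e-12)$root
}

theta_loglik <- function(Y, theta, phi) {
  tp <- outer(theta, phi)
  p1 <- 1 - exp(-tp)
  sum(log(p1[Y == 1 & p1 > 0])) - sum(tp[Y == 0])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @method tidy theta_fit
tidy.theta_fit <- function(x, ...) x$estimates

#' @export
#' @method glance theta_fit
glance.theta_fit <- function(x, ...) {
  new_tbl(
    n_sites = nrow(x$estimates),
    n_lengths = nrow(x$phi),
    iterations = x$iterations,
    converged = x$converged,
    loglik = x$loglik
  )
}

#' @export
print.theta_fit <- function(x, ...) {
  cat(sprintf(
    "<theta_fit> %d site(s), %d pooled fragment length(s), %s phi, %d iteration(s)%s\n",
    nrow(x$estimates), nrow(x$phi),
    if (x$fixed_phi) "fixed" else "estimated",
    x$iterations,
    if (x$converged) "" else " (NOT converged)"
  ))
  print(x$estimates)
  invisible(x)
}
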