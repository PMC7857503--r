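# Levenberg-Marquardt least squares via minpack.lm::nls.lm, with asymptotic
# standard errors from the Gauss-Newton approximation of the Hessian.
# `fn` maps a named parameter list to the residual vector (data - model).
# Using nls.lm directly (rather than the nls-object wrapper) keeps fits of
# noiseless synthetic data well-defined: zero-residual solutions are valid
# here, while nls-object construction rejects them.
.lmFit <- function(start, lower, fn, maxiter = 300) {
  r <- minpack.lm::nls.lm(
    par = start, lower = lower, fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter))
  if (!(r$info %in% 1:4))
    stop("no convergence: ", r$message)
  p <- unlist(r$par)
  n <- length(r$fvec)
  np <- length(p)
  s2 <- r$deviance / max(n - np, 1)
  se <- rep(NA_real_, np)
  vc <- tryCatch(solve(r$hessian), error = function(e) NULL)
  if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0) * s2)
  names(se) <- names(p)
  list(par = p, se = se, rss = r$deviance, n = n)
}
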