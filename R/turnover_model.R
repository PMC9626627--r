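# ---- allele-frequency turnover model ------------------------------------
#
# Ensemble-of-regression-trees model of allele-frequency turnover along
# environmental gradients. Per adaptive locus, a forest of CART regression
# trees (bootstrap over populations, random predictor subspace) is fitted
# to the locus's population frequencies; every split's impurity decrease
# is logged at its threshold. Split importances are accumulated into
# per-predictor monotone cumulative-importance curves, weighted by each
# locus's out-of-bag R^2, and globally normalized so total cumulative
# importance across predictors is 1. The curves transform climate values
# into a common "genomic composition" space in which genomic offsets are
# Euclidean distances.

# Fit one CART tree with rpart and return its splits as
# (predictor, threshold, delta) where delta is the decrease in the
# within-node sum of squares, recomputed from the frame deviances.
tree_splits <- function(y, X) {
  d <- data.frame(y = y, X, check.names = FALSE)
  ctl <- rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                              xval = 0, maxcompete = 0, maxsurrogate = 0,
                              maxdepth = 30)
  fit <- rpart::rpart(y ~ ., data = d, method = "anova", control = ctl)
  fr <- fit$frame
  internal <- fr$var != "<leaf>"
  if (!any(internal) || is.null(fit$splits))
    return(list(fit = fit,
                splits = data.frame(predictor = character(),
                                    threshold = numeric(),
                                    delta = numeric())))
  node <- as.integer(rownames(fr))
  dev <- stats::setNames(fr$dev, node)
  ni <- node[internal]
  delta <- dev[as.character(ni)] - dev[as.character(2L * ni)] -
    dev[as.character(2L * ni + 1L)]
  sp <- fit$splits   # one row per internal node, frame order
  list(fit = fit,
       splits = data.frame(predictor = rownames(sp),
                           threshold = unname(sp[, "index"]),
                           delta = pmax(unname(delta), 0),
                           stringsAsFactors = FALSE))
}

#' Fit an allele-frequency turnover model
#'
#' @param freqs an [allele_freq_matrix] restricted to the loci to model
#'   (typically the core adaptive set); missing cells mean-imputed.
#' @param env_pop populations x predictors `env_matrix`.
#' @param n_trees trees per locus (default 500).
#' @param mtry predictors sampled per tree (default `ceiling(P/3)`).
#' @param seed RNG seed; refitting with the same seed is reproducible.
#' @param min_pops minimum number of populations required (default 8).
#' @return object of class `"turnover_model"`: per predictor a sorted
#'   breakpoint/cumulative-value table, per-locus out-of-bag `r2` (loci
#'   with `R^2 <= 0` are dropped), locus weights, and the importance
#'   ranking. Total cumulative importance over predictors is 1.
#' @export
fit_turnover <- function(freqs, env_pop, n_trees = 500L, mtry = NULL,
                         seed = 1L, min_pops = 8L) {
  Y <- freqs$freq
  stopifnot(ncol(Y) >= 1, nrow(Y) == nrow(env_pop))
  if (ncol(Y) < 2 && ncol(Y) < 1) stop("need at least one locus")
  if (nrow(Y) < min_pops)
    stop("need at least ", min_pops, " populations")
  mu <- colMeans(Y, na.rm = TRUE)
  nab <- which(is.na(Y), arr.ind = TRUE)
  if (nrow(nab)) Y[nab] <- mu[nab[, 2]]
  X <- as.data.frame(unclass(env_pop))
  preds <- colnames(X)
  P <- length(preds)
  if (is.null(mtry)) mtry <- ceiling(P / 3)
  mtry <- max(1L, min(as.integer(mtry), P))
  n <- nrow(Y)
  set.seed(seed)

  loci <- colnames(Y)
  r2 <- stats::setNames(rep(NA_real_, length(loci)), loci)
  # per locus x predictor: accumulated split importance at thresholds
  acc <- vector("list", length(loci))
  names(acc) <- loci
  for (l in loci) {
    y <- Y[, l]
    vy <- stats::var(y)
    if (vy == 0) { r2[l] <- -Inf; next }
    oob_sum <- numeric(n); oob_n <- integer(n)
    splits <- vector("list", n_trees)
    for (t in seq_len(n_trees)) {
      bag <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(bag))
      vars_t <- sample(preds, mtry)
      ts <- tree_splits(y[bag], X[bag, vars_t, drop = FALSE])
      splits[[t]] <- ts$splits
      if (length(oob)) {
        pr <- stats::predict(ts$fit, newdata = X[oob, vars_t, drop = FALSE])
        oob_sum[oob] <- oob_sum[oob] + pr
        oob_n[oob] <- oob_n[oob] + 1L
      }
    }
    seen <- oob_n > 0
    mse <- mean((y[seen] - oob_sum[seen] / oob_n[seen])^2)
    r2[l] <- 1 - mse / vy
    acc[[l]] <- do.call(rbind, splits)
  }
  keep <- names(r2)[is.finite(r2) & r2 > 0]
  if (!length(keep))
    stop("no predictive turnover: all loci have out-of-bag R^2 <= 0")
  r2k <- r2[keep]
  w <- r2k / sum(r2k)

  # aggregate split importances: per locus, scale each predictor's split
  # deltas to (predictor share of locus importance) x R^2, then weight loci
  agg <- stats::setNames(vector("list", P), preds)
  for (l in keep) {
    s <- acc[[l]]
    if (!nrow(s)) next
    tot <- sum(s$delta)
    if (tot <= 0) next
    contrib <- s$delta / tot * r2k[l] * w[l]
    for (p in unique(s$predictor)) {
      i <- s$predictor == p
      agg[[p]] <- rbind(agg[[p]],
                        cbind(threshold = s$threshold[i],
                              imp = contrib[i]))
    }
  }
  curves <- lapply(preds, function(p) {
    a <- agg[[p]]
    if (is.null(a) || !nrow(a))
      return(data.frame(breakpoint = numeric(), cumulative = numeric()))
    o <- order(a[, "threshold"])
    bp <- a[o, "threshold"]; im <- a[o, "imp"]
    ub <- unique(bp)
    cum <- cumsum(vapply(ub, function(b) sum(im[bp == b]), 0))
    data.frame(breakpoint = ub, cumulative = cum)
  })
  names(curves) <- preds
  total <- sum(vapply(curves, function(cv)
    if (nrow(cv)) cv$cumulative[nrow(cv)] else 0, 0))
  if (total <= 0) stop("no predictive turnover: zero total importance")
  curves <- lapply(curves, function(cv) {
    cv$cumulative <- cv$cumulative / total
    cv
  })
  importance <- vapply(curves, function(cv)
    if (nrow(cv)) cv$cumulative[nrow(cv)] else 0, 0)
  structure(list(curves = curves, r2 = r2k, weights = w,
                 importance = importance, predictors = preds,
                 n_trees = n_trees, mtry = mtry, seed = seed,
                 dropped = setdiff(loci, keep)),
            class = "turnover_model")
}

#' @export
print.turnover_model <- function(x, ...) {
  cat("Turnover model:", length(x$r2), "loci (",
      length(x$dropped), "dropped ),", length(x$predictors),
      "predictors,", x$n_trees, "trees/locus\n")
  cat("Top predictors:\n")
  imp <- sort(x$importance, decreasing = TRUE)
  print(round(utils::head(imp, 6), 4))
  invisible(x)
}

# Right-continuous step evaluation of one cumulative-importance curve;
# values beyond the fitted range clamp to the boundary cumulative values.
eval_curve <- function(curve, x) {
  if (!nrow(curve)) return(rep(0, length(x)))
  i <- findInterval(x, curve$breakpoint)
  c(0, curve$cumulative)[i + 1L]
}

#' Transform climate into genomic-composition space
#'
#' Applies the fitted cumulative-importance functions predictor-wise:
#' entry (site, predictor) becomes `F_p(e)`, the cumulative importance at
#' the site's predictor value (right-continuous step function; values
#' below all breakpoints map to 0, above all breakpoints to the
#' predictor's total importance).
#'
#' @param object a `"turnover_model"`.
#' @param env sites x predictors matrix containing every model predictor.
#' @param ... unused.
#' @return sites x predictors numeric matrix in cumulative-importance
#'   units.
#' @export
predict.turnover_model <- function(object, env, ...) {
  miss <- setdiff(object$predictors, colnames(env))
  if (length(miss))
    stop("missing predictor column(s): ", paste(miss, collapse = ", "))
  e <- unclass(env)[, object$predictors, drop = FALSE]
  out <- vapply(object$predictors, function(p)
    eval_curve(object$curves[[p]], e[, p]), numeric(nrow(e)))
  if (nrow(e) == 1L) out <- matrix(out, nrow = 1,
                                   dimnames = list(rownames(e),
                                                   object$predictors))
  rownames(out) <- rownames(e)
  out
}

#' @rdname predict.turnover_model
#' @param model a `"turnover_model"`.
#' @export
transform_climate <- function(model, env) predict(model, env)

#' Ranked predictor importance
#'
#' Predictors ranked by total cumulative importance `F_p(+Inf)`,
#' descending; ties broken alphabetically.
#'
#' @param model a `"turnover_model"`.
#' @return data frame `predictor`, `importance` in rank order.
#' @export
variable_importance <- function(model) {
  imp <- model$importance
  o <- order(-imp, names(imp))
  data.frame(predictor = names(imp)[o], importance = unname(imp[o]),
             stringsAsFactors = FALSE)
}
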