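# Base learners for the boosting ensembles. Depth-1 learners are exhaustive
# decision stumps: every split point of every feature is scanned and the
# weighted misclassification error (classification) or weighted squared
# error (regression) is minimized exactly. Deeper trees delegate to rpart.

# Classification stump on y in {-1,+1} with weights w (summing to 1).
# Returns feature index, threshold, polarity: predict polarity where
# x > threshold, -polarity otherwise.
stump_class_fit <- function(X, y, w) {
  p <- ncol(X)
  best <- list(err = Inf)
  total_pos <- sum(w[y > 0])
  total_neg <- sum(w) - total_pos
  for (j in seq_len(p)) {
    x <- X[, j]
    o <- order(x)
    xs <- x[o]
    wpos <- cumsum(ifelse(y[o] > 0, w[o], 0))
    wneg <- cumsum(ifelse(y[o] > 0, 0, w[o]))
    # cut after position i: left x <= thr predicted -1, right predicted +1
    cuts <- which(diff(xs) > 0)
    errs_up <- c(total_neg, wpos[cuts] + (total_neg - wneg[cuts]))
    thrs <- c(xs[1] - 1, (xs[cuts] + xs[cuts + 1]) / 2)
    errs_dn <- sum(w) - errs_up
    for (side in 1:2) {
      errs <- if (side == 1) errs_up else errs_dn
      i <- which.min(errs)
      if (errs[i] < best$err - 1e-15) {
        best <- list(err = errs[i], feature = j, threshold = thrs[i],
                     polarity = if (side == 1) 1 else -1)
      }
    }
  }
  structure(best, class = "cps_stump")
}

stump_class_predict <- function(fit, X) {
  ifelse(X[, fit$feature] > fit$threshold, fit$polarity, -fit$polarity)
}

# Regression stump: piecewise-constant weighted least-squares fit.
stump_reg_fit <- function(X, y, w) {
  p <- ncol(X)
  wm <- sum(w * y) / sum(w)
  best <- list(sse = sum(w * (y - wm)^2), feature = 0L, threshold = -Inf,
               left = wm, right = wm)
  for (j in seq_len(p)) {
    x <- X[, j]
    o <- order(x)
    xs <- x[o]
    cw <- cumsum(w[o])
    cwy <- cumsum((w * y)[o])
    tw <- cw[length(cw)]
    twy <- cwy[length(cwy)]
    cuts <- which(diff(xs) > 0)
    if (!length(cuts)) next
    wl <- cw[cuts]; wr <- tw - wl
    sl <- cwy[cuts]; sr <- twy - sl
    sse <- sum(w * y^2) - sl^2 / wl - sr^2 / wr
    i <- which.min(sse)
    if (sse[i] < best$sse - 1e-15) {
      best <- list(sse = sse[i], feature = j,
                   threshold = (xs[cuts[i]] + xs[cuts[i] + 1]) / 2,
                   left = sl[i] / wl[i], right = sr[i] / wr[i])
    }
  }
  structure(best, class = "cps_reg_stump")
}

stump_reg_predict <- function(fit, X) {
  if (fit$feature == 0L) return(rep(fit$left, nrow(X)))
  ifelse(X[, fit$feature] > fit$threshold, fit$right, fit$left)
}

rpart_ctl <- function(depth) {
  rpart::rpart.control(maxdepth = depth, minsplit = 2, minbucket = 1,
                       cp = 0, xval = 0, maxsurrogate = 0,
                       maxcompete = 0)
}

weak_class_fit <- function(X, y, w, depth) {
  if (depth <= 1) return(stump_class_fit(X, y, w))
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(-1, 1))
  fit <- rpart::rpart(.y ~ ., data = df, weights = w / mean(w),
                      method = "class", control = rpart_ctl(depth))
  structure(list(fit = fit), class = "cps_rpart_class")
}

weak_class_predict <- function(fit, X) {
  if (inherits(fit, "cps_stump")) return(stump_class_predict(fit, X))
  pr <- predict(fit$fit, as.data.frame(X), type = "class")
  as.numeric(as.character(pr))
}

weak_reg_fit <- function(X, y, w, depth) {
  if (depth <= 1) return(stump_reg_fit(X, y, w))
  df <- as.data.frame(X)
  df$.y <- y
  fit <- rpart::rpart(.y ~ ., data = df, weights = w / mean(w),
                      method = "anova", control = rpart_ctl(depth))
  structure(list(fit = fit), class = "cps_rpart_reg")
}

weak_reg_predict <- function(fit, X) {
  if (inherits(fit, "cps_reg_stump")) return(stump_reg_predict(fit, X))
  as.numeric(predict(fit$fit, as.data.frame(X)))
}
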