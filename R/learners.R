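# Incremental learners. No streaming-learning package ships with the R
# stack used here, so the three canonical stream learners are implemented
# directly: Gaussian naive Bayes with running per-class moments, 1-nearest
# neighbour over the instances seen so far, and a basic Hoeffding tree
# (VFDT) with Gaussian attribute summaries at the leaves. Each learner is a
# closure pair: predict one row, then train on it.

# ---- Gaussian naive Bayes ------------------------------------------------

.nb_new <- function(p) {
  e <- new.env(parent = emptyenv())
  e$p <- p
  e$classes <- character()
  e$n <- numeric()          # per class
  e$mean <- list()          # per class: length-p running mean
  e$M2 <- list()            # per class: running sum of squared deviations
  e
}

.nb_train <- function(e, x, y) {
  k <- match(y, e$classes)
  if (is.na(k)) {
    e$classes <- c(e$classes, y)
    k <- length(e$classes)
    e$n[k] <- 0
    e$mean[[k]] <- numeric(e$p)
    e$M2[[k]] <- numeric(e$p)
  }
  e$n[k] <- e$n[k] + 1
  d <- x - e$mean[[k]]
  e$mean[[k]] <- e$mean[[k]] + d / e$n[k]
  e$M2[[k]] <- e$M2[[k]] + d * (x - e$mean[[k]])
}

.nb_predict <- function(e, x) {
  if (!length(e$classes)) return(NA_character_)
  total <- sum(e$n)
  score <- vapply(seq_along(e$classes), function(k) {
    v <- if (e$n[k] > 1) e$M2[[k]] / (e$n[k] - 1) else rep(1, e$p)
    v <- pmax(v, 1e-9)
    log(e$n[k] / total) -
      0.5 * sum(log(2 * pi * v) + (x - e$mean[[k]])^2 / v)
  }, numeric(1))
  e$classes[which.max(score)]
}

# ---- 1-nearest neighbour -------------------------------------------------

.knn_new <- function(p, capacity = 4096L) {
  e <- new.env(parent = emptyenv())
  e$X <- matrix(NA_real_, capacity, p)
  e$y <- character(capacity)
  e$n <- 0L
  e
}

.knn_train <- function(e, x, y) {
  if (e$n == nrow(e$X)) {           # grow geometrically
    e$X <- rbind(e$X, matrix(NA_real_, nrow(e$X), ncol(e$X)))
    e$y <- c(e$y, character(length(e$y)))
  }
  e$n <- e$n + 1L
  e$X[e$n, ] <- x
  e$y[e$n] <- y
}

.knn_predict <- function(e, x) {
  if (e$n == 0L) return(NA_character_)
  d2 <- rowSums(sweep(e$X[seq_len(e$n), , drop = FALSE], 2L, x)^2)
  e$y[which.min(d2)]
}

# ---- Hoeffding tree (basic VFDT) -----------------------------------------
# Leaves keep per-class counts and per-class per-feature running Gaussian
# moments. Every gracePeriod examples a leaf scans candidate thresholds
# (midpoints of the per-class means on each feature), estimates the
# information gain of the binary split from the Gaussian class-conditional
# CDFs, and splits when best - second best exceeds the Hoeffding bound
# sqrt(R^2 ln(1/delta) / (2 n)) (or the bound drops under the tie-break).

.ht_leaf <- function(p) {
  e <- new.env(parent = emptyenv())
  e$leaf <- TRUE
  e$p <- p
  e$classes <- character()
  e$n <- numeric()
  e$mean <- list()
  e$M2 <- list()
  e$sinceEval <- 0L
  e
}

.ht_new <- function(p, gracePeriod = 200L, delta = 1e-4, tieBreak = 0.1,
                    maxDepth = 12L) {
  e <- new.env(parent = emptyenv())
  e$root <- .ht_leaf(p)
  e$grace <- gracePeriod
  e$delta <- delta
  e$tie <- tieBreak
  e$maxDepth <- maxDepth
  e$p <- p
  e
}

.ht_sort <- function(tree, x) {
  node <- tree$root
  depth <- 1L
  while (!node$leaf) {
    node <- if (x[node$splitFeature] <= node$splitValue) node$left
            else node$right
    depth <- depth + 1L
  }
  list(node = node, depth = depth)
}

.entropy <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(0)
  pr <- counts[counts > 0] / tot
  -sum(pr * log2(pr))
}

.ht_try_split <- function(tree, node, depth) {
  if (depth >= tree$maxDepth || length(node$classes) < 2L) return()
  nTot <- sum(node$n)
  base <- .entropy(node$n)
  # per-attribute best threshold gain; the Hoeffding bound then compares the
  # two best ATTRIBUTES (thresholds on one attribute are not competitors)
  perFeature <- t(vapply(seq_len(node$p), function(j) {
    mu <- vapply(node$mean, `[[`, numeric(1), j)
    sd_ <- sqrt(pmax(vapply(seq_along(node$n), function(k)
      if (node$n[k] > 1) node$M2[[k]][j] / (node$n[k] - 1) else 1,
      numeric(1)), 1e-9))
    o <- order(mu)
    cand <- unique((mu[o][-length(mu)] + mu[o][-1]) / 2)
    gains <- vapply(cand, function(t) {
      nL <- node$n * stats::pnorm(t, mu, sd_)
      nR <- node$n - nL
      base - (sum(nL) * .entropy(nL) + sum(nR) * .entropy(nR)) / nTot
    }, numeric(1))
    k <- which.max(gains)
    c(gain = gains[k], value = cand[k])
  }, numeric(2)))
  o <- order(perFeature[, "gain"], decreasing = TRUE)
  best <- c(gain = unname(perFeature[o[1L], "gain"]), feature = o[1L],
            value = unname(perFeature[o[1L], "value"]))
  second <- if (node$p > 1L) unname(perFeature[o[2L], "gain"]) else 0
  if (best[["gain"]] <= 0) return()
  R <- log2(max(length(node$classes), 2))
  eps <- sqrt(R^2 * log(1 / tree$delta) / (2 * nTot))
  if (best[["gain"]] - second > eps || eps < tree$tie) {
    node$leaf <- FALSE
    node$splitFeature <- as.integer(best[["feature"]])
    node$splitValue <- best[["value"]]
    node$left <- .ht_leaf(node$p)
    node$right <- .ht_leaf(node$p)
    # fresh leaves predict NA until they see data; the harness falls back
    # to the stream majority for those slots
  }
}

.ht_train <- function(tree, x, y) {
  s <- .ht_sort(tree, x)
  node <- s$node
  k <- match(y, node$classes)
  if (is.na(k)) {
    node$classes <- c(node$classes, y)
    k <- length(node$classes)
    node$n[k] <- 0
    node$mean[[k]] <- numeric(node$p)
    node$M2[[k]] <- numeric(node$p)
  }
  node$n[k] <- node$n[k] + 1
  d <- x - node$mean[[k]]
  node$mean[[k]] <- node$mean[[k]] + d / node$n[k]
  node$M2[[k]] <- node$M2[[k]] + d * (x - node$mean[[k]])
  node$sinceEval <- node$sinceEval + 1L
  if (node$sinceEval >= tree$grace) {
    node$sinceEval <- 0L
    .ht_try_split(tree, node, s$depth)
  }
}

.ht_predict <- function(tree, x) {
  node <- .ht_sort(tree, x)$node
  if (!length(node$classes)) return(NA_character_)
  # naive-Bayes leaves: score with the leaf's Gaussian summaries once it has
  # seen enough data, otherwise fall back to the leaf majority
  total <- sum(node$n)
  if (total >= 10 && length(node$classes) > 1L) {
    score <- vapply(seq_along(node$classes), function(k) {
      v <- if (node$n[k] > 1) node$M2[[k]] / (node$n[k] - 1)
           else rep(1, node$p)
      v <- pmax(v, 1e-9)
      log(node$n[k] / total) -
        0.5 * sum(log(2 * pi * v) + (x - node$mean[[k]])^2 / v)
    }, numeric(1))
    return(node$classes[which.max(score)])
  }
  node$classes[which.max(node$n)]
}

# ---- common incremental interface ----------------------------------------

.incremental_learner <- function(kind, p) {
  switch(kind,
    naive_bayes = {
      e <- .nb_new(p)
      list(predict = function(x) .nb_predict(e, x),
           train = function(x, y) .nb_train(e, x, y))
    },
    knn1 = {
      e <- .knn_new(p)
      list(predict = function(x) .knn_predict(e, x),
           train = function(x, y) .knn_train(e, x, y))
    },
    hoeffding_tree = {
      e <- .ht_new(p)
      list(predict = function(x) .ht_predict(e, x),
           train = function(x, y) .ht_train(e, x, y))
    },
    stop("unknown incremental learner: ", kind)
  )
}
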