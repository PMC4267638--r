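# Small decision trees used as boosting base learners. Trees are fit with
# rpart (competing and surrogate splits disabled so the structure is
# unambiguous), then converted to an explicit node table that is used for
# all predictions and serialized to JSON. Missing-value routing is decided
# here, not by rpart: at each internal node, rows with a missing split
# variable go to the child minimizing the weighted training loss (fallback
# when no such rows exist: the child with the larger weight mass), and the
# stored route is reused at prediction time.

BOOST_EPS <- 1e-5

#' @noRd
stump_control <- function(maxdepth) {
  rpart::rpart.control(maxdepth = maxdepth, cp = -1, minsplit = 20L,
                       xval = 0L, maxcompete = 0L, maxsurrogate = 0L,
                       usesurrogate = 0L)
}

# fit one base tree; z is the working response (numeric for gentle boost,
# -1/+1 labels for real boost), w the current boosting weights
#' @noRd
fit_base_tree <- function(X, z, w, method, maxdepth = 2L) {
  df <- X
  df$.z <- if (method == "class") factor(z, levels = c(-1, 1)) else z
  fit <- rpart::rpart(.z ~ ., data = df, weights = w, method = method,
                      control = stump_control(maxdepth))
  extract_tree(fit, method)
}

# rpart object -> explicit node table
# columns: node id (1 root; children 2n, 2n+1), is_leaf, var, threshold,
# left_lt (left child takes x < threshold), na_left, yval (additive leaf
# contribution), aux (node mean on the routing scale), wt (weight mass)
#' @noRd
extract_tree <- function(fit, method) {
  fr <- fit$frame
  nodes <- as.integer(rownames(fr))
  is_leaf <- fr$var == "<leaf>"
  tr <- data.frame(node = nodes, is_leaf = is_leaf, var = NA_character_,
                   threshold = NA_real_, left_lt = NA, na_left = NA,
                   yval = NA_real_, aux = NA_real_, wt = fr$wt,
                   stringsAsFactors = FALSE)
  if (method == "anova") {
    tr$aux <- fr$yval
    tr$yval <- fr$yval
  } else {
    p <- fr$yval2[, 5L]  # P(class "+1"): levels are c(-1, 1)
    tr$aux <- p
    pc <- pmin(pmax(p, BOOST_EPS), 1 - BOOST_EPS)
    tr$yval <- 0.5 * log(pc / (1 - pc))
  }
  if (any(!is_leaf)) {
    sp <- fit$splits
    ii <- which(!is_leaf)
    if (nrow(sp) != length(ii))
      stop("unexpected rpart splits layout", call. = FALSE)  # guarded by control
    tr$var[ii] <- rownames(sp)
    tr$threshold[ii] <- sp[, "index"]
    tr$left_lt[ii] <- sp[, "ncat"] < 0
  }
  tr
}

#' @noRd
tree_row <- function(tree, node) which(tree$node == node)

# decide na_left for every internal node from the training data, walking
# top-down; z01 is the response on the routing scale (matching aux)
#' @noRd
route_missing <- function(tree, X, z01, w) {
  walk <- function(node, idx) {
    r <- tree_row(tree, node)
    if (tree$is_leaf[r]) return()
    v <- X[[tree$var[r]]][idx]
    lr <- tree_row(tree, 2L * node)
    rr <- tree_row(tree, 2L * node + 1L)
    nai <- idx[is.na(v)]
    if (length(nai)) {
      loss_l <- sum(w[nai] * (z01[nai] - tree$aux[lr])^2)
      loss_r <- sum(w[nai] * (z01[nai] - tree$aux[rr])^2)
      tree$na_left[r] <<- loss_l <= loss_r
    } else {
      tree$na_left[r] <<- tree$wt[lr] >= tree$wt[rr]
    }
    go_left <- if (tree$left_lt[r]) v < tree$threshold[r] else v >= tree$threshold[r]
    go_left[is.na(v)] <- tree$na_left[r]
    walk(2L * node, idx[go_left])
    walk(2L * node + 1L, idx[!go_left])
  }
  walk(1L, seq_len(nrow(X)))
  tree
}

# additive contribution of one tree for every row of X
#' @noRd
predict_tree <- function(tree, X) {
  out <- numeric(nrow(X))
  walk <- function(node, idx) {
    if (!length(idx)) return()
    r <- tree_row(tree, node)
    if (tree$is_leaf[r]) {
      out[idx] <<- tree$yval[r]
      return()
    }
    v <- X[[tree$var[r]]][idx]
    go_left <- if (tree$left_lt[r]) v < tree$threshold[r] else v >= tree$threshold[r]
    na_left <- tree$na_left[r]
    if (is.na(na_left)) na_left <- TRUE
    go_left[is.na(v)] <- na_left
    walk(2L * node, idx[go_left])
    walk(2L * node + 1L, idx[!go_left])
  }
  walk(1L, seq_len(nrow(X)))
  out
}
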