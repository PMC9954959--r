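#' Gini impurity of a node
#'
#' `1 - sum(p_k^2)` over the class proportions of the node: 0 for a pure
#' node, 0.5 at worst for two classes.
#'
#' @param class_counts non-negative integer vector of per-class counts.
#' @return Impurity in `[0, 1)`.
#' @examples
#' gini(c(3, 1))  # 0.375
#' @export
gini <- function(class_counts) {
  if (any(class_counts < 0)) stop("counts must be non-negative")
  total <- sum(class_counts)
  if (total == 0) stop("cannot compute impurity of an empty node")
  1 - sum((class_counts / total)^2)
}

node_counts <- function(y) c(benign = sum(y == "benign"),
                             malignant = sum(y == "malignant"))

#' Best binary split of a node
#'
#' Scans every candidate sign and every threshold midway between consecutive
#' distinct observed values of that sign, and returns the split maximizing
#' the Gini impurity decrease: parent impurity minus the sample-weighted mean
#' impurity of the two children (`sign < threshold` vs `>=`). Coded
#' sub-features are treated as ordinal numerics. Ties are broken by the
#' lowest sign index, then the lowest threshold.
#'
#' @param x numeric matrix of sign columns for the samples in the node.
#' @param y benign/malignant labels of those samples.
#' @param candidate_signs integer column indices to consider (default all).
#' @return A list with `sign` (column index), `threshold`,
#'   `impurity_decrease`; or `NULL` when no split has a positive decrease
#'   (including the pure-node case).
#' @export
best_split <- function(x, y, candidate_signs = seq_len(ncol(x))) {
  x <- as.matrix(x)
  y <- as.character(y)
  n <- nrow(x)
  parent <- gini(node_counts(y))
  if (parent == 0 || n < 2) return(NULL)

  best <- NULL
  for (j in candidate_signs) {
    v <- x[, j]
    uv <- sort(unique(v))
    if (length(uv) < 2) next
    thr <- (uv[-length(uv)] + uv[-1]) / 2
    # cumulative class counts over samples ordered by v give all left-child
    # counts in one pass
    ord <- order(v)
    ym <- y[ord] == "malignant"
    vb <- v[ord]
    cum_m <- cumsum(ym)
    cum_n <- seq_len(n)
    # index of the last sample strictly below each threshold
    left_n <- findInterval(thr, vb)
    left_m <- cum_m[left_n]
    right_n <- n - left_n
    right_m <- cum_m[n] - left_m
    gl <- 1 - ((left_m / left_n)^2 + ((left_n - left_m) / left_n)^2)
    gr <- 1 - ((right_m / right_n)^2 + ((right_n - right_m) / right_n)^2)
    dec <- parent - (left_n * gl + right_n * gr) / n
    for (t in seq_along(thr)) {
      if (dec[t] <= 1e-12) next
      if (is.null(best) || dec[t] > best$impurity_decrease + 1e-12)
        best <- list(sign = j, threshold = thr[t], impurity_decrease = dec[t])
    }
  }
  best
}

leaf_node <- function(y) {
  cnt <- node_counts(y)
  # majority class; tie goes to malignant (screening posture)
  cls <- if (cnt["malignant"] >= cnt["benign"]) "malignant" else "benign"
  list(leaf = TRUE, class = cls, n = length(y),
       counts = cnt, purity = max(cnt) / sum(cnt))
}

#' Grow a Gini guideline tree
#'
#' CART-style binary tree on the coded sonographic signs. Growth is
#' best-first: at every step the frontier leaf whose best split yields the
#' largest node-fraction-weighted impurity decrease is expanded. Without a
#' budget this continues until every leaf is pure or admits no
#' positive-decrease split; with `max_splits` set (the prepruning used for
#' the clinical guideline is 7) growth stops at the budget, so the budget is
#' spent where it pays most. Leaves carry the majority class; ties go to
#' malignant.
#'
#' @param x data frame or matrix of sign columns (coded values).
#' @param y benign/malignant labels.
#' @param max_splits optional prepruning budget on the number of internal
#'   nodes; `NULL` grows the full tree.
#' @param sign_names column names used when rendering; defaults to
#'   `colnames(x)`.
#' @return A `"guideline_tree"`: recursive `root` node, `n_splits`, `pruned`
#'   flag, `max_splits`, `sign_names`, and `importance` (per-sign total
#'   weighted impurity decrease).
#' @examples
#' tbl <- generate_nodules(n_total = 150, n_malignant = 100, seed = 2)
#' tr <- grow_tree(tbl[paste0("P", 1:27)], tbl$label, max_splits = 7)
#' tr
#' @export
grow_tree <- function(x, y, max_splits = NULL, sign_names = colnames(x)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.character(y)
  if (is.null(sign_names)) sign_names <- paste0("V", seq_len(ncol(x)))
  n_root <- nrow(x)
  stopifnot(n_root >= 1)

  # frontier entries: sample index set + precomputed best split and its
  # root-fraction-weighted decrease (the expansion priority)
  make_entry <- function(ix) {
    sp <- if (length(ix) >= 2) best_split(x[ix, , drop = FALSE], y[ix])
          else NULL
    list(ix = ix, split = sp,
         priority = if (is.null(sp)) -Inf
                    else sp$impurity_decrease * length(ix) / n_root)
  }

  frontier <- list(make_entry(seq_len(n_root)))
  splits <- list()   # expansion records: entry + child entry ids
  node_id <- 1L
  ids <- c(1L)
  children <- list() # id -> c(left_id, right_id) or NULL for leaf
  entries <- list(); entries[[1]] <- frontier[[1]]
  open <- c(1L)
  n_splits <- 0L
  importance <- stats::setNames(numeric(ncol(x)), sign_names)

  repeat {
    if (!length(open)) break
    if (!is.null(max_splits) && n_splits >= max_splits) break
    pri <- vapply(open, function(id) entries[[id]]$priority, 0)
    if (all(pri == -Inf)) break
    id <- open[which.max(pri)]
    e <- entries[[id]]
    open <- setdiff(open, id)
    sp <- e$split
    go_left <- x[e$ix, sp$sign] < sp$threshold
    l_ix <- e$ix[go_left]; r_ix <- e$ix[!go_left]
    lid <- node_id + 1L; rid <- node_id + 2L; node_id <- node_id + 2L
    entries[[lid]] <- make_entry(l_ix)
    entries[[rid]] <- make_entry(r_ix)
    children[[id]] <- c(lid, rid)
    open <- c(open, lid, rid)
    n_splits <- n_splits + 1L
    importance[sp$sign] <- importance[sp$sign] + e$priority
  }

  build <- function(id) {
    e <- entries[[id]]
    kid <- if (id <= length(children)) children[[id]] else NULL
    if (is.null(kid)) return(leaf_node(y[e$ix]))
    sp <- e$split
    list(leaf = FALSE, sign = sp$sign, sign_name = sign_names[sp$sign],
         threshold = sp$threshold, impurity_decrease = sp$impurity_decrease,
         n = length(e$ix),
         left = build(kid[1]), right = build(kid[2]))
  }

  structure(list(root = build(1L), n_splits = n_splits,
                 pruned = !is.null(max_splits), max_splits = max_splits,
                 sign_names = sign_names, importance = importance),
            class = "guideline_tree")
}

#' @export
print.guideline_tree <- function(x, ...) {
  cat(sprintf("Guideline tree: %d splits%s\n", x$n_splits,
              if (x$pruned) sprintf(" (prepruned, budget %d)", x$max_splits)
              else " (fully grown)"))
  cat(guideline_text(x), sep = "\n")
  invisible(x)
}

#' Predict classes with a guideline tree
#'
#' @param object a `"guideline_tree"`.
#' @param newdata data frame or matrix with the sign columns the tree was
#'   grown on.
#' @param ... unused.
#' @return Factor with levels benign/malignant.
#' @export
predict.guideline_tree <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  one <- function(node, row) {
    while (!node$leaf)
      node <- if (row[node$sign] < node$threshold) node$left else node$right
    node$class
  }
  out <- vapply(seq_len(nrow(x)), function(k) one(object$root, x[k, ]), "")
  factor(out, levels = c("benign", "malignant"))
}

#' Classification loss of a tree
#'
#' Fraction of misclassified samples; on the training table this is the
#' resubstitution error reported for the guideline diagrams.
#'
#' @param tree a fitted `"guideline_tree"`.
#' @param x,y sign columns and labels to evaluate on.
#' @return Loss in `[0, 1]`.
#' @export
classification_loss <- function(tree, x, y) {
  mean(as.character(predict(tree, x)) != as.character(y))
}

#' Rank sonographic signs by impurity decrease
#'
#' Grows the unpruned tree and attributes to each sign the total
#' node-fraction-weighted Gini decrease of the nodes splitting on it. Signs
#' never chosen score 0; the importances sum to the tree's total impurity
#' decrease (root impurity minus the weighted leaf impurity).
#'
#' @param x,y sign columns and labels.
#' @return A `"sign_ranking"` data frame with columns `sign`, `importance`,
#'   sorted descending.
#' @export
rank_signs <- function(x, y) {
  tr <- grow_tree(x, y, max_splits = NULL)
  out <- data.frame(sign = names(tr$importance),
                    importance = as.numeric(tr$importance))
  out <- out[order(-out$importance, seq_len(nrow(out))), ]
  rownames(out) <- NULL
  class(out) <- c("sign_ranking", "data.frame")
  out
}

#' Top-K signs of a ranking
#'
#' @param ranking a [rank_signs()] result.
#' @param k how many signs to keep (13 reproduces the reduced input set used
#'   alongside the full 27-sign one).
#' @return Character vector of sign names.
#' @export
top_signs <- function(ranking, k = 13) {
  utils::head(ranking$sign, k)
}

#' Render a guideline tree as an indented flowchart
#'
#' Branch conditions are phrased as sets of sub-feature codes (for a
#' threshold `t` on an ordinal sign, the codes `< t` and `>= t`), the form in
#' which the clinical guideline is read; leaves state the diagnosis and its
#' training purity.
#'
#' @param tree a `"guideline_tree"`.
#' @return Character vector, one line per row of the flowchart.
#' @export
guideline_text <- function(tree) {
  fmt_codes <- function(thr, left) {
    if (isTRUE(all.equal(thr %% 1, 0.5))) {
      # midpoint between integer codes: phrase as a code set boundary
      if (left) sprintf("code <= %d", floor(thr))
      else sprintf("code >= %d", ceiling(thr))
    } else {
      # continuous sign (size, diameter ratio)
      if (left) sprintf("value < %.4g", thr) else sprintf("value >= %.4g", thr)
    }
  }
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf)
      return(sprintf("%s=> %s (n=%d, purity %.2f)", pad, node$class,
                     node$n, node$purity))
    c(sprintf("%s%s [%s]:", pad, node$sign_name,
              fmt_codes(node$threshold, TRUE)),
      walk(node$left, indent + 1),
      sprintf("%s%s [%s]:", pad, node$sign_name,
              fmt_codes(node$threshold, FALSE)),
      walk(node$right, indent + 1))
  }
  walk(tree$root, 0)
}

#' Export a guideline tree as a Graphviz DOT graph
#'
#' @param tree a `"guideline_tree"`.
#' @return A single DOT-format string (`digraph`), with internal nodes
#'   labeled by sign and threshold and edges by the code condition.
#' @export
guideline_dot <- function(tree) {
  lines <- c("digraph guideline {", "  node [shape=box];")
  counter <- new.env(); counter$i <- 0L
  walk <- function(node) {
    counter$i <- counter$i + 1L
    my <- sprintf("n%d", counter$i)
    if (node$leaf) {
      lines <<- c(lines, sprintf(
        "  %s [label=\"%s\\nn=%d\", shape=ellipse];", my, node$class, node$n))
    } else {
      lines <<- c(lines, sprintf("  %s [label=\"%s\"];", my, node$sign_name))
      lid <- walk(node$left)
      rid <- walk(node$right)
      lines <<- c(lines,
        sprintf("  %s -> %s [label=\"< %.3g\"];", my, lid, node$threshold),
        sprintf("  %s -> %s [label=\">= %.3g\"];", my, rid, node$threshold))
    }
    my
  }
  walk(tree$root)
  paste(c(lines, "}"), collapse = "\n")
}
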