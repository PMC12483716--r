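# Synthetic person-by-item data generators: explanatory item response data
# with simple or complex fixed-effect structures, and "tree-truth" data whose
# fixed part is a single explicit decision tree, with controllable
# inter-predictor correlation.  Every generator is a pure function of
# (spec, seed).

#' Simulation design specification
#'
#' Defaults encode the canonical study conditions: 13 person-level
#' predictors (4 nominal with 2 or 3 categories, 9 standard-normal
#' continuous), 3 nominal item-level predictors, logit coefficients drawn
#' once from Uniform(-1, 1), intercept 0, and person/item random-intercept
#' variances in {0, 0.7, 2.8}.
#'
#' @param n_persons number of persons (study levels: 100 or 400).
#' @param n_items number of items (study levels: 10 or 30).
#' @param structure `"simple"` (main effects only) or `"complex"` (adds
#'   person-by-item interaction terms).
#' @param sigma2_person,sigma2_item random-intercept variances.
#' @param target_median_corr target median of within-level pairwise
#'   predictor correlations (study levels: 0.003 or 0.400).
#' @param n_person_nominal,n_person_continuous,n_item_nominal predictor
#'   counts (defaults 4, 9, 3).
#' @param coef_range coefficient range for the uniform draws.
#' @param intercept fixed intercept (default 0).
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_persons = 100, n_items = 10,
                            structure = c("simple", "complex"),
                            sigma2_person = 0.7, sigma2_item = 0.7,
                            target_median_corr = 0.003,
                            n_person_nominal = 4, n_person_continuous = 9,
                            n_item_nominal = 3,
                            coef_range = c(-1, 1), intercept = 0) {
  structure_ <- match.arg(structure)
  stopifnot(n_persons >= 2, n_items >= 2,
            sigma2_person >= 0, sigma2_item >= 0,
            all(is.finite(coef_range)))
  structure(list(
    n_persons = as.integer(n_persons), n_items = as.integer(n_items),
    structure = structure_,
    sigma2_person = sigma2_person, sigma2_item = sigma2_item,
    target_median_corr = target_median_corr,
    n_person_nominal = as.integer(n_person_nominal),
    n_person_continuous = as.integer(n_person_continuous),
    n_item_nominal = as.integer(n_item_nominal),
    coef_range = coef_range, intercept = intercept
  ), class = "simulation_spec")
}

# jittered exchangeable latent correlation matrix, projected to a valid
# correlation matrix.  Pairs involving a thresholded (nominal) variable get
# an inflated latent entry to offset categorization attenuation.
latent_corr <- function(p, is_nominal, rho, jitter_sd = 0.03) {
  R <- matrix(rho, p, p)
  if (any(is_nominal)) {
    infl <- outer(is_nominal, is_nominal, `|`)
    R[infl] <- pmin(0.95, rho / 0.8)
  }
  noise <- matrix(stats::rnorm(p * p, 0, jitter_sd), p, p)
  noise <- (noise + t(noise)) / 2
  R <- R + noise
  diag(R) <- 1
  R[R > 0.98] <- 0.98
  R[R < -0.98] <- -0.98
  e <- eigen(R, symmetric = TRUE)
  vals <- pmax(e$values, 1e-6)
  R <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R))
  R / tcrossprod(d)
}

draw_table <- function(n, n_nominal, n_continuous, k_cats, rho, prefix) {
  p <- n_nominal + n_continuous
  is_nom <- c(rep(TRUE, n_nominal), rep(FALSE, n_continuous))
  R <- latent_corr(p, is_nom, rho)
  L <- chol(R)
  Zl <- matrix(stats::rnorm(n * p), n, p) %*% L
  out <- list()
  for (k in seq_len(n_nominal)) {
    K <- k_cats[k]
    cuts <- stats::qnorm(seq_len(K - 1) / K)
    codes <- findInterval(Zl[, k], cuts) + 1L
    out[[paste0(prefix, "nom", k)]] <- factor(paste0("c", codes),
                                              levels = paste0("c", seq_len(K)))
  }
  for (k in seq_len(n_continuous)) {
    out[[paste0(prefix, "con", k)]] <- Zl[, n_nominal + k]
  }
  as.data.frame(out)
}

#' Generate correlated person and item predictor tables
#'
#' Continuous predictors are standard normal; nominal predictors have 2 or 3
#' categories obtained by thresholding latent Gaussians.  Cross-predictor
#' dependence is induced by a jittered exchangeable Gaussian copula;
#' candidate draws are rejected until the achieved median of within-level
#' pairwise correlations (numeric-coded) falls within 0.05 of the target
#' and the interquartile range is plausible.  Cross-level pairs are not
#' calibrated: in a fully crossed design their long-format sample
#' correlation is structurally zero.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed.
#' @param max_attempts accept-reject budget (default 100).
#' @return list with `person` (data frame, rownames `P...`), `item`
#'   (rownames `I...`), `schema` (an `eirmrf_schema` for the 16 predictors),
#'   `achieved` (median/IQR of within-level correlations), `attempts`.
#' @export
gen_predictors <- function(spec, seed, max_attempts = 100L) {
  stopifnot(inherits(spec, "simulation_spec"))
  target <- spec$target_median_corr
  for (attempt in seq_len(max_attempts)) {
    res <- with_local_seed(sub_seed(seed, attempt), {
      k_person <- sample(2:3, spec$n_person_nominal, replace = TRUE)
      k_item <- sample(2:3, spec$n_item_nominal, replace = TRUE)
      person <- draw_table(spec$n_persons, spec$n_person_nominal,
                           spec$n_person_continuous, k_person, target, "p")
      item <- draw_table(spec$n_items, spec$n_item_nominal, 0, k_item, target, "i")
      list(person = person, item = item, k_person = k_person, k_item = k_item)
    })
    # no near-zero-variance predictors in an accepted draw: every nominal
    # column must show at least two categories, with the most frequent one
    # at most 19 times as common as the runner-up
    degenerate <- any(vapply(c(res$person, res$item), function(v) {
      if (!is.factor(v)) return(FALSE)
      tab <- sort(table(v), decreasing = TRUE)
      length(tab[tab > 0]) < 2 || tab[[1]] / tab[[2]] > 19
    }, logical(1)))
    if (degenerate) next
    num_p <- sapply(res$person, as.numeric)
    num_i <- sapply(res$item, as.numeric)
    cors <- suppressWarnings(
      c(stats::cor(num_p)[upper.tri(diag(ncol(num_p)))],
        stats::cor(num_i)[upper.tri(diag(ncol(num_i)))])
    )
    cors <- cors[is.finite(cors)]
    med <- stats::median(cors)
    iqr <- stats::IQR(cors)
    if (abs(med - target) <= 0.05 && iqr >= 0.01 && iqr <= 0.20) {
      rownames(res$person) <- sprintf("P%04d", seq_len(spec$n_persons))
      rownames(res$item) <- sprintf("I%03d", seq_len(spec$n_items))
      schema <- predictor_schema(c(
        lapply(seq_len(spec$n_person_nominal), function(k) list(
          name = paste0("pnom", k), level = "person", kind = "nominal",
          categories = paste0("c", seq_len(res$k_person[k])), reference = "c1"
        )),
        lapply(seq_len(spec$n_person_continuous), function(k) list(
          name = paste0("pcon", k), level = "person", kind = "continuous"
        )),
        lapply(seq_len(spec$n_item_nominal), function(k) list(
          name = paste0("inom", k), level = "item", kind = "nominal",
          categories = paste0("c", seq_len(res$k_item[k])), reference = "c1"
        ))
      ))
      return(list(
        person = res$person, item = res$item, schema = schema,
        achieved = list(median = med, iqr = iqr), attempts = attempt
      ))
    }
  }
  stop_eirmrf(sprintf(
    "could not reach target median correlation %.3f in %d attempts",
    target, max_attempts
  ), "generation_error")
}

# dummy-code a predictor table (first category reference), returning a
# numeric matrix with named columns
dummy_code <- function(df) {
  cols <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.factor(v)) {
      for (lv in levels(v)[-1]) {
        cols[[paste0(nm, ".", lv)]] <- as.numeric(v == lv)
      }
    } else {
      cols[[nm]] <- as.numeric(v)
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  m
}

#' Fixed linear predictor over the person-by-item grid
#'
#' `"simple"`: intercept plus main effects of every (dummy-coded) person and
#' item predictor, coefficients i.i.d. Uniform(-1, 1).  `"complex"`: the
#' simple terms plus an interaction block -- each continuous person
#' predictor crossed with the dummies of the first item predictor, and each
#' person nominal dummy crossed with the dummies of the second item
#' predictor -- with Uniform(-1, 1) coefficients.  Coefficients are drawn
#' once per call and intended to be held fixed across replications.
#'
#' @param tables output of [gen_predictors()].
#' @param structure `"simple"` or `"complex"`.
#' @param seed coefficient seed.
#' @param intercept fixed intercept (default 0).
#' @param coef_range uniform coefficient range for the main effects.
#' @param interaction_share for the complex structure, the interaction
#'   block's variance contribution as a fraction of the main-effect
#'   variance (default 0.25): the raw Uniform(-1, 1) interaction draws are
#'   rescaled so the complex structure's total latent variance sits
#'   moderately above the simple structure's instead of dominating it.
#' @return list with `eta` (persons x items matrix), `coefficients` (named
#'   list of the draws), `structure`.
#' @export
linear_predictor <- function(tables, structure = c("simple", "complex"), seed,
                             intercept = 0, coef_range = c(-1, 1),
                             interaction_share = 0.25) {
  structure_ <- match.arg(structure)
  Xp <- dummy_code(tables$person)
  Xi <- dummy_code(tables$item)
  J <- nrow(Xp)
  I <- nrow(Xi)

  coefs <- with_local_seed(sub_seed(seed, 17), {
    runifc <- function(n) stats::runif(n, coef_range[1], coef_range[2])
    beta_p <- stats::setNames(runifc(ncol(Xp)), colnames(Xp))
    beta_i <- stats::setNames(runifc(ncol(Xi)), colnames(Xi))
    inter <- NULL
    if (structure_ == "complex") {
      cont_cols <- grep("^pcon", colnames(Xp), value = TRUE)
      pnom_cols <- grep("^pnom", colnames(Xp), value = TRUE)
      i1_cols <- grep("^inom1\\.", colnames(Xi), value = TRUE)[1]
      i2_cols <- grep("^inom2\\.", colnames(Xi), value = TRUE)[1]
      g1 <- expand.grid(p = cont_cols, i = i1_cols, stringsAsFactors = FALSE)
      g2 <- expand.grid(p = pnom_cols, i = i2_cols, stringsAsFactors = FALSE)
      g <- rbind(g1, g2)
      inter <- data.frame(g, coef = runifc(nrow(g)), stringsAsFactors = FALSE)
    }
    list(beta_person = beta_p, beta_item = beta_i, interactions = inter)
  })

  eta_main <- intercept +
    outer(as.numeric(Xp %*% coefs$beta_person),
          as.numeric(Xi %*% coefs$beta_item), `+`)
  eta <- eta_main
  if (!is.null(coefs$interactions)) {
    eta_int <- 0 * eta_main
    for (r in seq_len(nrow(coefs$interactions))) {
      pc <- coefs$interactions$p[r]
      ic <- coefs$interactions$i[r]
      eta_int <- eta_int + coefs$interactions$coef[r] * outer(Xp[, pc], Xi[, ic])
    }
    v_int <- stats::var(as.numeric(eta_int))
    if (v_int > 0) {
      scale <- sqrt(interaction_share * stats::var(as.numeric(eta_main)) / v_int)
      coefs$interactions$coef <- coefs$interactions$coef * scale
      eta <- eta_main + scale * eta_int
    }
  }
  dimnames(eta) <- list(rownames(tables$person), rownames(tables$item))
  list(eta = eta, coefficients = coefs, structure = structure_,
       intercept = intercept,
       person_names = names(tables$person), item_names = names(tables$item))
}

#' Evaluate a generated fixed-effect surface on arbitrary feature rows
#'
#' Returns the generating linear predictor as a function of a feature data
#' frame (factors carrying the generator's category levels), so properties
#' of the truth -- e.g. interaction strength via [h_statistic()] -- can be
#' probed on counterfactual feature combinations.
#'
#' @param lp output of [linear_predictor()].
#' @return `function(df) -> eta` on the logit scale.
#' @export
linear_predictor_fn <- function(lp) {
  force(lp)
  function(df) {
    Xp <- dummy_code(df[, lp$person_names, drop = FALSE])
    Xi <- dummy_code(df[, lp$item_names, drop = FALSE])
    bp <- lp$coefficients$beta_person
    bi <- lp$coefficients$beta_item
    eta <- lp$intercept +
      as.numeric(Xp[, names(bp), drop = FALSE] %*% bp) +
      as.numeric(Xi[, names(bi), drop = FALSE] %*% bi)
    inter <- lp$coefficients$interactions
    if (!is.null(inter)) {
      for (r in seq_len(nrow(inter))) {
        eta <- eta + inter$coef[r] * Xp[, inter$p[r]] * Xi[, inter$i[r]]
      }
    }
    eta
  }
}

# long-format predictor frame for the full person-by-item grid
assemble_long <- function(tables) {
  J <- nrow(tables$person)
  I <- nrow(tables$item)
  pj <- rep(seq_len(J), each = I)
  ii <- rep(seq_len(I), times = J)
  df <- cbind(
    data.frame(person_id = rownames(tables$person)[pj],
               item_id = rownames(tables$item)[ii],
               stringsAsFactors = FALSE),
    tables$person[pj, , drop = FALSE],
    tables$item[ii, , drop = FALSE]
  )
  rownames(df) <- NULL
  df
}

make_response_table <- function(df, schema) {
  structure(
    df,
    schema = schema,
    n_persons = length(unique(df$person_id)),
    n_items = length(unique(df$item_id)),
    class = c("response_table", "data.frame")
  )
}

#' Generate binary responses from the item response model
#'
#' `y ~ Bernoulli(invlogit(eta + theta_j + b_i))` with fresh
#' `theta_j ~ N(0, sigma2_person)` and `b_i ~ N(0, sigma2_item)` per call
#' (random effects are regenerated at each replication; the fixed part is
#' not).
#'
#' @param tables output of [gen_predictors()].
#' @param eta persons x items matrix of fixed linear predictors.
#' @param sigma2_person,sigma2_item random-intercept variances (>= 0).
#' @param seed replication seed.
#' @return a `response_table` in long format with all predictors attached
#'   and attribute `random_effects` (the generated `theta`, `b`).
#' @export
gen_eirm_dataset <- function(tables, eta, sigma2_person, sigma2_item, seed) {
  stopifnot(sigma2_person >= 0, sigma2_item >= 0)
  J <- nrow(tables$person)
  I <- nrow(tables$item)
  stopifnot(nrow(eta) == J, ncol(eta) == I)
  out <- with_local_seed(seed, {
    theta <- stats::rnorm(J, 0, sqrt(sigma2_person))
    b <- stats::rnorm(I, 0, sqrt(sigma2_item))
    lin <- eta + outer(theta, b, `+`)
    pr <- invlogit(as.numeric(t(lin)))      # row-major: person-major long order
    y <- stats::rbinom(length(pr), 1, pr)
    list(theta = theta, b = b, y = y, pr = pr)
  })
  df <- assemble_long(tables)
  df <- cbind(df[, 1:2], y = out$y, df[, -(1:2), drop = FALSE])
  tab <- make_response_table(df, tables$schema)
  attr(tab, "random_effects") <- list(theta = out$theta, b = out$b)
  attr(tab, "true_prob") <- out$pr
  tab
}

#' Generate a random "true" decision tree over selected predictors
#'
#' Selects 2 of the item-level and 5 of the person-level predictors
#' uniformly at random and grows a random binary tree of depth 3--5:
#' internal nodes split a uniformly chosen selected feature (continuous
#' thresholds uniform over the central 80% of the node's observed values;
#' nominal splits send a random nonempty proper category subset left);
#' leaves carry probabilities Uniform(0.05, 0.95).  Splits that would leave
#' a side empty on the observed rows are resampled.
#'
#' @param tables output of [gen_predictors()].
#' @param seed tree seed.
#' @param depth_range inclusive range of the target depth (default 3:5).
#' @param leaf_range leaf probability range (default `c(0.05, 0.95)`).
#' @param gamma0,gamma1 mapping of the tree probability into the linear
#'   predictor of the generating model (defaults -2 and 4, so tree outputs
#'   0..1 span logits -2..2).
#' @return a `true_tree`: list with `root` (nested nodes), `selected`
#'   (feature names), `gamma0`, `gamma1`, `depth`.
#' @export
gen_true_tree <- function(tables, seed, depth_range = c(3L, 5L),
                          leaf_range = c(0.05, 0.95),
                          gamma0 = -2, gamma1 = 4) {
  long <- assemble_long(tables)
  person_preds <- names(tables$person)
  item_preds <- names(tables$item)

  with_local_seed(sub_seed(seed, 97), {
    sel_item <- sample(item_preds, 2)
    sel_person <- sample(person_preds, 5)
    selected <- c(sel_item, sel_person)
    d_target <- sample(seq(depth_range[1], depth_range[2]), 1)

    new_leaf <- function() {
      list(type = "leaf", prob = stats::runif(1, leaf_range[1], leaf_range[2]))
    }
    grow <- function(rows, depth) {
      if (depth >= d_target || length(rows) < 2) return(new_leaf())
      for (try in 1:20) {
        feat <- sample(selected, 1)
        v <- long[[feat]][rows]
        if (is.factor(v)) {
          cats <- levels(v)
          k <- sample(seq_len(length(cats) - 1), 1)
          left_cats <- sample(cats, k)
          left <- as.character(v) %in% left_cats
        } else {
          qs <- stats::quantile(v, c(0.1, 0.9), names = FALSE)
          thr <- stats::runif(1, qs[1], qs[2])
          left <- v <= thr
        }
        if (any(left) && any(!left)) {
          node <- list(type = "split", feature = feat)
          if (is.factor(v)) node$left_cats <- left_cats else node$threshold <- thr
          node$left <- grow(rows[left], depth + 1)
          node$right <- grow(rows[!left], depth + 1)
          return(node)
        }
      }
      new_leaf()
    }
    root <- grow(seq_len(nrow(long)), 0)
    structure(list(
      root = root, selected = selected, sel_item = sel_item,
      sel_person = sel_person, gamma0 = gamma0, gamma1 = gamma1,
      depth = d_target
    ), class = "true_tree")
  })
}

#' Tree-predicted probabilities
#'
#' @param tree a `true_tree`.
#' @param newdata data frame containing the tree's feature columns.
#' @return probability vector from the leaves.
#' @export
predict_tree <- function(tree, newdata) {
  stopifnot(inherits(tree, "true_tree"))
  n <- nrow(newdata)
  out <- numeric(n)
  recurse <- function(node, idx) {
    if (length(idx) == 0) return(invisible(NULL))
    if (node$type == "leaf") {
      out[idx] <<- node$prob
      return(invisible(NULL))
    }
    v <- newdata[[node$feature]][idx]
    left <- if (!is.null(node$left_cats)) {
      as.character(v) %in% node$left_cats
    } else {
      as.numeric(v) <= node$threshold
    }
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(tree$root, seq_len(n))
  out
}

#' Serialize a true tree to JSON
#' @param tree a `true_tree`.
#' @return JSON string.
#' @export
serialize_tree <- function(tree) {
  as.character(jsonlite::toJSON(unclass(tree), auto_unbox = TRUE, digits = NA))
}

#' @export
print.true_tree <- function(x, ...) {
  cat(sprintf("True tree: depth %d over features {%s}; gamma0 = %g, gamma1 = %g\n",
              x$depth, paste(x$selected, collapse = ", "), x$gamma0, x$gamma1))
  invisible(x)
}

#' Generate binary responses from the tree-truth model
#'
#' `y ~ Bernoulli(invlogit(gamma0 + gamma1 * p_tree(x) + theta_j + b_i))`.
#'
#' @param tree a `true_tree`.
#' @param tables output of [gen_predictors()].
#' @param sigma2_person,sigma2_item random-intercept variances.
#' @param seed replication seed.
#' @return a `response_table` (long format, predictors attached).
#' @export
gen_eirmtree_dataset <- function(tree, tables, sigma2_person, sigma2_item, seed) {
  stopifnot(sigma2_person >= 0, sigma2_item >= 0)
  long <- assemble_long(tables)
  p_tree <- predict_tree(tree, long)
  J <- nrow(tables$person)
  I <- nrow(tables$item)
  pj <- rep(seq_len(J), each = I)
  ii <- rep(seq_len(I), times = J)
  out <- with_local_seed(seed, {
    theta <- stats::rnorm(J, 0, sqrt(sigma2_person))
    b <- stats::rnorm(I, 0, sqrt(sigma2_item))
    lin <- tree$gamma0 + tree$gamma1 * p_tree + theta[pj] + b[ii]
    y <- stats::rbinom(length(lin), 1, invlogit(lin))
    list(theta = theta, b = b, y = y)
  })
  df <- cbind(long[, 1:2], y = out$y, long[, -(1:2), drop = FALSE])
  tab <- make_response_table(df, tables$schema)
  attr(tab, "random_effects") <- list(theta = out$theta, b = out$b)
  attr(tab, "p_tree") <- p_tree
  tab
}

# impurity-decrease importance of the single true tree, with the tree's own
# probabilities as soft labels; unselected features receive exactly 0
tree_impurity_importance <- function(tree, data) {
  s <- predict_tree(tree, data)
  n <- nrow(data)
  imp <- numeric(0)
  gini <- function(idx) {
    p <- mean(s[idx])
    2 * p * (1 - p)
  }
  recurse <- function(node, idx) {
    if (node$type == "leaf" || length(idx) == 0) return(invisible(NULL))
    v <- data[[node$feature]][idx]
    left <- if (!is.null(node$left_cats)) {
      as.character(v) %in% node$left_cats
    } else {
      as.numeric(v) <= node$threshold
    }
    nl <- sum(left)
    nr <- sum(!left)
    if (nl > 0 && nr > 0) {
      dec <- (length(idx) / n) *
        (gini(idx) - (nl / length(idx)) * gini(idx[left]) -
           (nr / length(idx)) * gini(idx[!left]))
      cur <- if (node$feature %in% names(imp)) imp[[node$feature]] else 0
      imp[node$feature] <<- cur + max(dec, 0)
    }
    recurse(node$left, idx[left])
    recurse(node$right, idx[!left])
  }
  recurse(tree$root, seq_len(n))
  imp
}

#' Reference interpretable-ML values implied by a true tree
#'
#' Two reference definitions are available.  `mode = "tree"` evaluates the
#' interpretation suite against the tree's own prediction function:
#' impurity-decrease importance of the single tree (exactly 0 for
#' unselected features), partial dependence, accumulated local effects and
#' the per-feature overall H-statistic.  `mode = "rf"` first draws
#' noise-free outcomes (`Bernoulli(invlogit(gamma0 + gamma1 p_tree))`, no
#' person/item random effects) and fits a probability forest to them, then
#' computes the same suite from that forest, so reference and empirical
#' values share the forest machinery and unselected features receive small
#' but nonzero importances.  The grids and bin edges are returned so
#' empirical curves can be evaluated at identical points.
#'
#' @param tree a `true_tree`.
#' @param tables output of [gen_predictors()].
#' @param mode `"rf"` (default) or `"tree"`; see above.
#' @param rf_params forest settings for `mode = "rf"`.
#' @param pd_grid_size grid size for continuous partial dependence
#'   (default 15).
#' @param ale_bins quantile bins for accumulated local effects (default 10).
#' @param background_sample row cap for the partial-dependence / ALE
#'   background (default 300, seeded); the selected row indices are
#'   returned so empirical curves can average over the identical rows.
#' @param h_sample evaluation rows for the H-statistic (default 100,
#'   seeded, likewise returned for reuse).
#' @param seed seed for the row subsamples and the `mode = "rf"` outcome
#'   draw.
#' @return list with `importance` (named, all features), `pd` (list of
#'   `effect_curve`s), `ale` (list, continuous features), `h` (named),
#'   `pd_grids`, `ale_edges`, `background_rows`, `h_rows`, `features`,
#'   `selected`, `mode`.
#' @export
true_interpretation_values <- function(tree, tables, mode = c("rf", "tree"),
                                       rf_params = forest_params(
                                         mtry = 4, n_trees = 500, seed = 1
                                       ),
                                       pd_grid_size = 15,
                                       ale_bins = 10,
                                       background_sample = 300,
                                       h_sample = 100,
                                       seed = 1L) {
  mode <- match.arg(mode)
  long <- assemble_long(tables)
  feats <- c(names(tables$person), names(tables$item))
  data <- long[, feats, drop = FALSE]

  if (mode == "tree") {
    pfun <- function(df) predict_tree(tree, df)
    imp_sel <- tree_impurity_importance(tree, data)
    importance <- stats::setNames(rep(0, length(feats)), feats)
    importance[names(imp_sel)] <- imp_sel
  } else {
    p_tree <- predict_tree(tree, data)
    y_true <- with_local_seed(sub_seed(seed, 3), {
      stats::rbinom(nrow(data), 1, invlogit(tree$gamma0 + tree$gamma1 * p_tree))
    })
    pars <- rf_params
    pars$seed <- sub_seed(seed, 4)
    ref_fit <- fit_forest(data, y_true, pars, degenerate_ok = TRUE)
    pfun <- forest_predict_fn(ref_fit)
    importance <- stats::setNames(rep(0, length(feats)), feats)
    got <- ref_fit$gini_importance[feats]
    importance[!is.na(got)] <- got[!is.na(got)]
  }

  # fixed evaluation rows, shared between reference and empirical suites so
  # curve and H comparisons are made over identical feature values
  n <- nrow(data)
  bg_rows <- if (background_sample < n) {
    sort(with_local_seed(sub_seed(seed, 10), sample.int(n, background_sample)))
  } else seq_len(n)
  h_rows <- if (h_sample < n) {
    sort(with_local_seed(sub_seed(seed, 11), sample.int(n, h_sample)))
  } else seq_len(n)
  bg <- data[bg_rows, , drop = FALSE]
  hd <- data[h_rows, , drop = FALSE]

  pd_grids <- lapply(stats::setNames(feats, feats), function(f) {
    x <- data[[f]]
    if (is.factor(x)) levels(x)
    else unique(stats::quantile(x, seq(0, 1, length.out = pd_grid_size),
                                names = FALSE, type = 7))
  })
  pd <- lapply(stats::setNames(feats, feats), function(f) {
    partial_dependence(pfun, bg, f, grid = pd_grids[[f]])
  })

  cont <- feats[!vapply(data, is.factor, logical(1))]
  ale_edges <- lapply(stats::setNames(cont, cont), function(f) {
    unique(stats::quantile(data[[f]], seq(0, 1, length.out = ale_bins + 1),
                           names = FALSE, type = 7))
  })
  ale <- lapply(stats::setNames(cont, cont), function(f) {
    accumulated_local_effects(pfun, bg, f, edges = ale_edges[[f]])
  })

  h <- vapply(stats::setNames(feats, feats), function(f) {
    h_statistic(pfun, hd, f, n_sample = nrow(hd))$value
  }, numeric(1))

  list(
    importance = importance, pd = pd, ale = ale, h = h,
    pd_grids = pd_grids, ale_edges = ale_edges,
    background_rows = bg_rows, h_rows = h_rows,
    features = feats, selected = tree$selected, mode = mode
  )
}
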