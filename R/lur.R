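# Land-use regression: buffer predictor extraction, correlation screening,
# iterative stepwise fitting, hold-out validation and raster prediction of
# the PM2.5 surface. Ordinary least-squares fits go through stats::lm; the
# screening and removal-until-convergence procedure is implemented here.

buffer_families <- c("MROAD", "SROAD", "TAL", "VEG", "INDU", "WAT",
                     "RAR", "POP")
met_vars <- c("PRS", "PRS_Sea", "WIN", "TEM", "RHU", "PRE_1h")

# Land-use classes contributing to each buffer share family. VEG is the
# ecological share (forest/green plus water); POP uses residential land
# share as a population proxy.
family_classes <- list(VEG = c("ecological", "water"), INDU = "industrial",
                       WAT = "water", RAR = "arable", POP = "residential")

#' A priori direction of effect of each predictor family on PM2.5
#'
#' @return Named numeric vector of +1/-1 per variable family (road and
#'   built-land densities positive; ecological shares and meteorological
#'   variables negative).
#' @export
assumed_signs <- function() {
  c(MROAD = 1, SROAD = 1, TAL = 1, VEG = -1, INDU = 1, WAT = -1,
    RAR = -1, POP = 1, PRS = -1, PRS_Sea = -1, WIN = -1, TEM = -1,
    RHU = -1, PRE_1h = -1)
}

variable_family <- function(name) {
  if (name %in% met_vars) return(name)
  fam <- sub("[0-9]+$", "", name)
  if (fam %in% buffer_families && fam != name) return(fam)
  NA_character_
}

#' Extract buffer predictors around one site
#'
#' For each radius, land-use shares are the class area intersected with
#' the circular buffer divided by the buffer area, and road densities are
#' the road length inside the buffer divided by the buffer area. Values
#' are independent of how the parcel mosaic is tessellated (merging
#' parcels of one class changes nothing); an empty intersection yields 0.
#'
#' @param site List or one-row data.frame with `x`, `y` (m).
#' @param parcels A `parcel_set` or a parcel data.frame (rectangles with
#'   `class`).
#' @param roads Road segment table (`road_class`, `x1`, `y1`, `x2`, `y2`).
#' @param radii Positive ascending buffer radii (m).
#' @param circle_n Vertices of the polygonal circle approximation.
#' @return Named numeric vector `<FAMILY><radius>` covering MROAD, SROAD,
#'   TAL (m/m^2) and VEG, INDU, WAT, RAR, POP (fractions).
#' @export
extract_buffer_variables <- function(site, parcels, roads,
                                     radii = c(500, 1000, 1500, 2000,
                                               3000, 4000, 5000),
                                     circle_n = 128L) {
  if (inherits(parcels, "parcel_set")) parcels <- parcels$parcels
  if (is.unsorted(radii) || any(radii <= 0))
    stop("`radii` must be positive and ascending")
  sx <- site$x; sy <- site$y
  out <- numeric(0)
  for (r in radii) {
    circ <- circle_poly(sx, sy, r, circle_n)
    barea <- poly_area(circ)
    # bbox prefilter: parcels that can touch the buffer
    near <- parcels$xmax >= sx - r & parcels$xmin <= sx + r &
      parcels$ymax >= sy - r & parcels$ymin <= sy + r
    areas <- stats::setNames(numeric(length(unique(parcels$class))),
                             unique(parcels$class))
    idx <- which(near)
    for (i in idx) {
      cl <- clip_rect(circ, parcels$xmin[i], parcels$ymin[i],
                      parcels$xmax[i], parcels$ymax[i])
      a <- poly_area(cl)
      if (a > 0) areas[parcels$class[i]] <- areas[parcels$class[i]] + a
    }
    shares <- vapply(c("VEG", "INDU", "WAT", "RAR", "POP"), function(f) {
      sum(areas[intersect(family_classes[[f]], names(areas))]) / barea
    }, numeric(1))
    rl <- c(main = 0, secondary = 0)
    nearr <- which(pmax(roads$x1, roads$x2) >= sx - r &
                     pmin(roads$x1, roads$x2) <= sx + r &
                     pmax(roads$y1, roads$y2) >= sy - r &
                     pmin(roads$y1, roads$y2) <= sy + r)
    for (i in nearr) {
      len <- seg_circle_len(roads$x1[i], roads$y1[i], roads$x2[i],
                            roads$y2[i], sx, sy, r)
      rl[[roads$road_class[i]]] <- rl[[roads$road_class[i]]] + len
    }
    vals <- c(MROAD = rl[["main"]] / barea,
              SROAD = rl[["secondary"]] / barea,
              TAL = (rl[["main"]] + rl[["secondary"]]) / barea,
              shares)
    names(vals) <- paste0(names(vals), r)
    out <- c(out, vals)
  }
  out
}

# Buffer predictors for every site: one row per site.
site_predictor_table <- function(sites, parcels, roads, radii,
                                 circle_n = 128L) {
  rows <- lapply(seq_len(nrow(sites)), function(i)
    extract_buffer_variables(sites[i, ], parcels, roads, radii, circle_n))
  out <- as.data.frame(do.call(rbind, rows))
  cbind(site_id = sites$site_id, out, stringsAsFactors = FALSE)
}

#' Assemble the LUR design matrix for a panel
#'
#' Joins the per-site buffer predictors onto the site-month panel and
#' appends the meteorological columns.
#'
#' @param panel Panel data.frame (`site_id`, `month`, met columns).
#' @param site_predictors Output of the per-site extraction (column
#'   `site_id` plus `<FAMILY><radius>` columns).
#' @return data.frame of predictors aligned with `panel` rows.
#' @export
build_design <- function(panel, site_predictors) {
  m <- match(panel$site_id, site_predictors$site_id)
  if (any(is.na(m))) stop("panel has sites without extracted predictors")
  X <- site_predictors[m, setdiff(colnames(site_predictors), "site_id"),
                       drop = FALSE]
  met <- intersect(met_vars, colnames(panel))
  rownames(X) <- NULL
  cbind(X, panel[, met, drop = FALSE])
}

#' Screen predictors by correlation
#'
#' Two-stage screening on the monthly panel: (1) within each subcategory
#' (one buffer family across its radii; meteorological variables are
#' singleton subcategories) keep the member with the largest absolute
#' Pearson correlation with the response; (2) rank the winners by |r| and,
#' walking down the ranking, drop any variable correlated above `rcut`
#' (in absolute value) with an already-accepted one. Constant columns are
#' excluded with a warning.
#'
#' @param design Predictor data.frame from [build_design()].
#' @param y Response vector (PM2.5).
#' @param rcut Collinearity cutoff (default 0.6).
#' @return List: `retained` (accepted names in rank order), `winners`
#'   (family winners before pruning), `correlations` (named r with the
#'   response).
#' @export
screen_variables <- function(design, y, rcut = 0.6) {
  if (length(y) < 3L) stop("need at least 3 records")
  if (stats::sd(y) == 0) stop("constant response")
  X <- as.matrix(design)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant predictor column(s) excluded: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  r <- drop(stats::cor(X, y))
  fams <- vapply(colnames(X), variable_family, character(1))
  keep <- unlist(lapply(split(seq_along(fams), fams), function(ii)
    ii[which.max(abs(r[ii]))]), use.names = FALSE)
  winners <- colnames(X)[keep][order(-abs(r[keep]))]
  accepted <- character(0)
  for (v in winners) {
    if (length(accepted) == 0L) { accepted <- v; next }
    rx <- abs(stats::cor(X[, v], X[, accepted, drop = FALSE]))
    if (all(rx <= rcut)) accepted <- c(accepted, v)
  }
  list(retained = accepted, winners = winners, correlations = r)
}

#' Fit the land-use regression by iterative backward removal
#'
#' Fits a multiple linear regression on the screened variables, removes
#' every variable whose two-sided t-test p-value exceeds `alpha` (and,
#' when `enforce_sign = TRUE`, every variable whose coefficient sign
#' contradicts [assumed_signs()]), refits, and repeats until no removal
#' occurs. The loop terminates in at most `length(variables)` iterations.
#'
#' @param design Predictor data.frame.
#' @param y Response vector.
#' @param variables Character vector of candidate variable names (e.g.
#'   `screen_variables(...)$retained`).
#' @param alpha Removal threshold on the p-value (default 0.10, i.e. a 90%
#'   confidence requirement).
#' @param enforce_sign Remove coefficients contradicting the a priori
#'   direction. Off by default: the reference model this package emulates
#'   retains a precipitation term whose sign contradicts the a priori
#'   table, so enforcement would not reproduce it.
#' @return Object of class `lur_model`: coefficients, retained variables,
#'   `r_squared`, `adj_r_squared`, the underlying `lm` fit, and the data
#'   needed to recompute every reported statistic.
#' @export
fit_lur <- function(design, y, variables, alpha = 0.10,
                    enforce_sign = FALSE) {
  stopifnot(length(y) == nrow(design))
  vars <- variables
  signs <- assumed_signs()
  fit <- NULL
  repeat {
    if (length(vars) == 0L) {
      fit <- stats::lm(y ~ 1)
      break
    }
    dat <- cbind(y = y, design[, vars, drop = FALSE])
    fit <- stats::lm(y ~ ., data = dat)
    sm <- summary(fit)$coefficients
    pv <- sm[-1, 4]
    bad <- pv > alpha
    if (enforce_sign) {
      fam <- vapply(vars, variable_family, character(1))
      want <- signs[fam]
      bad <- bad | (!is.na(want) & sign(sm[-1, 1]) != want)
    }
    if (!any(bad)) break
    vars <- vars[!bad]
  }
  sm <- summary(fit)
  structure(list(coefficients = stats::coef(fit), retained = vars,
                 r_squared = if (length(vars)) sm$r.squared else 0,
                 adj_r_squared = if (length(vars)) sm$adj.r.squared else 0,
                 alpha = alpha, enforce_sign = enforce_sign,
                 n = length(y), fit = fit,
                 design = design[, vars, drop = FALSE], y = y),
            class = "lur_model")
}

#' @export
print.lur_model <- function(x, ...) {
  cat("LUR model:", x$n, "records,", length(x$retained),
      "retained predictor(s)\n")
  print(round(x$coefficients, 4))
  cat("R^2 =", round(x$r_squared, 4),
      " adj R^2 =", round(x$adj_r_squared, 4), "\n")
  if (!is.null(x$cv))
    cat("CV: mean absolute error rate =", round(x$cv$mae_rate, 4),
        " RMSE =", round(x$cv$rmse, 4), "\n")
  invisible(x)
}

#' Hold-out cross-validation of a model specification
#'
#' Randomly splits the records (default 75% modelling / 25% validation),
#' refits the specification on the modelling part, and evaluates the
#' hold-out mean absolute error rate `mean(|yhat - y| / |y|)` and RMSE.
#' Hold-out records with `y == 0` are skipped in the error rate with a
#' warning.
#'
#' @param design Predictor data.frame.
#' @param y Response vector (length >= 8).
#' @param variables Variables of the model specification.
#' @param seed Split seed (same seed, same split and metrics).
#' @param train_frac Modelling fraction (default 0.75).
#' @return List: `mae_rate`, `rmse`, `train_idx`.
#' @export
cross_validate <- function(design, y, variables, seed = 1L,
                           train_frac = 0.75) {
  n <- length(y)
  if (n < 8L) stop("need at least 8 records for a 75/25 split")
  set.seed(seed)
  tr <- sort(sample(n, round(train_frac * n)))
  te <- setdiff(seq_len(n), tr)
  dat <- cbind(y = y, design[, variables, drop = FALSE])
  fit <- stats::lm(y ~ ., data = dat[tr, , drop = FALSE])
  yhat <- stats::predict(fit, newdata = dat[te, , drop = FALSE])
  err <- yhat - y[te]
  nz <- y[te] != 0
  if (!all(nz)) warning("hold-out records with PM2.5 == 0 skipped in MAE rate")
  list(mae_rate = mean(abs(err[nz]) / abs(y[te][nz])),
       rmse = sqrt(mean(err^2)), train_idx = tr)
}

# 2-D FFT convolution of matrix A with kernel K (zero padding; output
# aligned with A, kernel centred on each cell).
conv2_fft <- function(A, K) {
  pr <- stats::nextn(nrow(A) + nrow(K) - 1, c(2, 3, 5))
  pc <- stats::nextn(ncol(A) + ncol(K) - 1, c(2, 3, 5))
  Ap <- matrix(0, pr, pc); Ap[seq_len(nrow(A)), seq_len(ncol(A))] <- A
  Kp <- matrix(0, pr, pc); Kp[seq_len(nrow(K)), seq_len(ncol(K))] <- K
  full <- Re(stats::fft(stats::fft(Ap) * stats::fft(Kp), inverse = TRUE)) /
    (pr * pc)
  r0 <- (nrow(K) - 1) %/% 2; c0 <- (ncol(K) - 1) %/% 2
  full[r0 + seq_len(nrow(A)), c0 + seq_len(ncol(A))]
}

circle_kernel <- function(r, res) {
  k <- floor(r / res)
  off <- (-k:k) * res
  M <- outer(off, off, function(a, b) as.numeric(a^2 + b^2 <= r^2))
  M
}

#' Predict the PM2.5 surface from a fitted LUR model
#'
#' Evaluates the model on a regular grid over the region. Buffer-share
#' layers are computed by rasterizing the parcel mosaic (cell-centre
#' class) on the padded extent and taking circular focal means at each
#' model radius; road-density layers use rasterized road length.
#' Meteorological terms are evaluated at `met` (default 0, the annual
#' mean of standardized anomalies), so the default surface is the
#' annual-mean PM2.5 field.
#'
#' @param model A `lur_model`.
#' @param parcels A `parcel_set`.
#' @param roads Road segment table.
#' @param res Cell size in metres (default 100).
#' @param met Named numeric vector of met values, or `NULL` for zeros.
#' @return A `pm_raster` of PM2.5 (ug/m^3) over the region.
#' @export
predict_surface <- function(model, parcels, roads, res = 100, met = NULL) {
  stopifnot(inherits(model, "lur_model"), inherits(parcels, "parcel_set"))
  ext <- parcels$extent; pad <- parcels$pad
  cf <- model$coefficients
  vars <- model$retained
  n_out <- as.integer(round(ext / res))
  # padded grid (row 1 = top) used for focal sums
  n_padcell <- as.integer(ceiling(pad / res))
  n_all <- n_out + 2L * n_padcell
  x0 <- -n_padcell * res
  grid_class <- matrix(NA_character_, n_all, n_all)
  pk <- parcels$parcels
  col_of <- function(x) pmin(pmax(floor((x - x0) / res) + 1, 1), n_all)
  row_of <- function(y) pmin(pmax(n_all - floor((y - x0) / res), 1), n_all)
  for (i in seq_len(nrow(pk))) {
    c0 <- col_of(pk$xmin[i] + res / 2); c1 <- col_of(pk$xmax[i] - res / 2)
    r1 <- row_of(pk$ymin[i] + res / 2); r0 <- row_of(pk$ymax[i] - res / 2)
    if (c1 >= c0 && r1 >= r0) grid_class[r0:r1, c0:c1] <- pk$class[i]
  }
  road_len <- NULL
  need_road <- any(vapply(vars, variable_family, character(1)) %in%
                     c("MROAD", "SROAD", "TAL"))
  if (need_road) {
    road_len <- list(main = matrix(0, n_all, n_all),
                     secondary = matrix(0, n_all, n_all))
    step <- res / 4
    for (i in seq_len(nrow(roads))) {
      L <- sqrt((roads$x2[i] - roads$x1[i])^2 + (roads$y2[i] - roads$y1[i])^2)
      nstep <- max(1L, ceiling(L / step))
      t <- (seq_len(nstep) - 0.5) / nstep
      px <- roads$x1[i] + t * (roads$x2[i] - roads$x1[i])
      py <- roads$y1[i] + t * (roads$y2[i] - roads$y1[i])
      rr <- row_of(py); cc <- col_of(px)
      cls <- roads$road_class[i]
      idx <- cbind(rr, cc)
      addl <- L / nstep
      for (q in seq_len(nrow(idx)))
        road_len[[cls]][idx[q, 1], idx[q, 2]] <-
          road_len[[cls]][idx[q, 1], idx[q, 2]] + addl
    }
  }
  pred <- matrix(cf[["(Intercept)"]], n_out, n_out)
  sel <- n_padcell + seq_len(n_out)
  for (v in vars) {
    fam <- variable_family(v)
    if (fam %in% met_vars) {
      val <- if (!is.null(met) && fam %in% names(met)) met[[fam]] else 0
      pred <- pred + cf[[v]] * val
      next
    }
    r <- as.numeric(sub("^[A-Za-z_]+", "", v))
    K <- circle_kernel(r, res)
    layer <- if (fam %in% c("MROAD", "SROAD", "TAL")) {
      src <- switch(fam, MROAD = road_len$main, SROAD = road_len$secondary,
                    TAL = road_len$main + road_len$secondary)
      conv2_fft(src, K) / (sum(K) * res^2)
    } else {
      ind <- matrix(as.numeric(grid_class %in% family_classes[[fam]]),
                    n_all, n_all)
      conv2_fft(ind, K) / sum(K)
    }
    pred <- pred + cf[[v]] * layer[sel, sel]
  }
  make_raster(pred, 0, 0, res)
}
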