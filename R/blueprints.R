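# Planted connectivity-state blueprints for the synthetic cohort.

set_block <- function(z, rois_a, rois_b, value) {
  z[rois_a, rois_b] <- value
  z[rois_b, rois_a] <- value
  z
}

#' Five planted connectivity-state blueprints
#'
#' Each blueprint is a target 10 x 10 Fisher-z connectivity pattern over the
#' default ROI set, realizing the qualitative structure of the five recurrent
#' states:
#'
#' 1. **Global integration, MPFC apart** — high connectivity among all
#'    regions of the three networks except the MPFC, whose coupling to DAN
#'    and FPN is near zero; intra-network connectivity preserved.
#' 2. **DMN-FPN coupling, DAN segregated** — high DMN-FPN connectivity, both
#'    anticorrelated with a DAN that keeps high intra-network connectivity.
#' 3. **Low connectivity** — the weakest inter-network coupling of all
#'    states, intra-network connectivity preserved.
#' 4. **FPN hemispheric split** — right FPN couples to the DMN and left FPN
#'    to the DAN, with the two FPN halves decoupled from each other.
#' 5. **DAN-FPN coupling, DMN segregated** — high DAN-FPN connectivity,
#'    anticorrelated with a DMN showing its strongest intra-network
#'    connectivity.
#'
#' The z-levels are free design parameters chosen for between-state
#' separability; they are not empirical estimates.
#'
#' @param z_high high-connectivity level (also intra-network level).
#' @param z_low near-zero inter-network level.
#' @param z_anti anticorrelation level.
#' @param roi_set the [roi_set()] blueprints are expressed on.
#' @return List of 5 objects of class `state_blueprint`, each with `name`,
#'   `description`, `z` (matrix, `NA` diagonal), `correlation`
#'   (positive-definite repaired correlation matrix).
#' @export
default_blueprints <- function(z_high = 0.6, z_low = 0.05, z_anti = -0.3,
                               roi_set = default_roi_set()) {
  rois <- roi_set$roi_names
  net <- roi_set$network_of
  dan <- rois[net == "DAN"]
  dmn <- rois[net == "DMN"]
  fpn <- rois[net == "FPN"]
  fpn_l <- fpn[grepl("l$", fpn)]
  fpn_r <- fpn[grepl("r$", fpn)]
  base <- function(fill) {
    z <- matrix(fill, 10L, 10L, dimnames = list(rois, rois))
    z
  }
  intra <- function(z, level = z_high) {
    for (members in list(dan, dmn, fpn)) z <- set_block(z, members, members,
                                                        level)
    z
  }

  z1 <- base(z_high)
  z1 <- set_block(z1, "MPFC", c(dan, fpn), z_low)

  z2 <- base(z_low)
  z2 <- set_block(z2, dmn, fpn, z_high)
  z2 <- set_block(z2, dan, c(dmn, fpn), z_anti)
  z2 <- intra(z2)

  z3 <- intra(base(z_low))

  z4 <- base(z_low)
  z4 <- set_block(z4, fpn_r, dmn, z_high)
  z4 <- set_block(z4, fpn_l, dan, z_high)
  z4 <- intra(z4)
  z4 <- set_block(z4, fpn_l, fpn_r, 0)           # hemispheric FPN decoupling
  z4 <- set_block(z4, fpn_l, fpn_l, z_high)
  z4 <- set_block(z4, fpn_r, fpn_r, z_high)

  z5 <- base(z_low)
  z5 <- set_block(z5, dan, fpn, z_high)
  z5 <- set_block(z5, dmn, c(dan, fpn), z_anti)
  z5 <- intra(z5)
  z5 <- set_block(z5, dmn, dmn, min(0.8, z_high + 0.2))  # strongest DMN intra

  zs <- list(z1, z2, z3, z4, z5)
  descriptions <- c(
    "high connectivity across the three networks except the MPFC",
    "DMN-FPN coupling with an anticorrelated, segregated DAN",
    "lowest inter-network connectivity, intra-network preserved",
    "right FPN coupled to DMN, left FPN to DAN, FPN halves decoupled",
    "DAN-FPN coupling with an anticorrelated DMN of high intra-network FC")
  lapply(seq_along(zs), function(i) {
    z <- zs[[i]]
    diag(z) <- NA_real_
    state_blueprint(name = i, z = z, description = descriptions[i])
  })
}

#' Construct a state blueprint
#'
#' Validates symmetry, converts the target z-pattern to a correlation matrix
#' (`tanh`), and repairs it to the nearest positive-definite correlation
#' matrix (`Matrix::nearPD`). The repair must not move any entry by 0.05 or
#' more, ensuring that the sampled data actually carry the stated pattern.
#'
#' @param name state label (integer).
#' @param z symmetric matrix of target z-values, `NA` diagonal.
#' @param description free-text tag.
#' @param max_repair largest tolerated entrywise change during the
#'   positive-definite repair.
#' @return An object of class `state_blueprint`.
#' @export
state_blueprint <- function(name, z, description = "", max_repair = 0.05) {
  v <- vectorize_upper_triangle(z)   # validates symmetry
  r <- tanh(z)
  diag(r) <- 1
  repaired <- as.matrix(Matrix::nearPD(r, corr = TRUE,
                                       posd.tol = 1e-6)$mat)
  dimnames(repaired) <- dimnames(r)
  delta <- max(abs(repaired - r))
  if (delta >= max_repair)
    stop("positive-definite repair moved an entry by ", signif(delta, 3),
         " (>= ", max_repair, "); blueprint levels are too extreme")
  structure(list(name = name, z = z, description = description,
                 correlation = repaired, repair_delta = delta),
            class = "state_blueprint")
}

#' @export
print.state_blueprint <- function(x, ...) {
  cat(sprintf("State blueprint %s: %s (max PD-repair change %.3g)\n",
              x$name, x$description, x$repair_delta))
  invisible(x)
}

#' Blueprint centroid feature vectors
#'
#' @param blueprints list of `state_blueprint`s.
#' @return k x 45 matrix of target z feature vectors.
#' @export
blueprint_features <- function(blueprints) {
  m <- t(vapply(blueprints, function(b) vectorize_upper_triangle(b$z),
                numeric(45L)))
  rownames(m) <- paste0("state", vapply(blueprints, `[[`, numeric(1L),
                                        "name"))
  m
}
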