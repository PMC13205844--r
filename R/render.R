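# 2D parametric face renderer. Faces are drawn as filled head silhouettes with
# feature strokes (hairline, brows, eyes, nose, lips, creases) routed exactly
# through the template landmarks, so every landmark sits on an intensity edge
# and the localization task is learnable from pixels alone.
#
# The canvas is an environment holding one H x W matrix per channel in [0, 1];
# keeping single references lets patch sub-assignments modify in place, which
# is what makes full-resolution rendering fast enough for whole cohorts.
# Coordinates are 0-based pixel centers (x = column, y = row).

.canvas <- function(W, H, color = c(0.88, 0.89, 0.90)) {
  cv <- new.env(parent = emptyenv())
  cv$W <- W; cv$H <- H
  cv$ch1 <- matrix(color[1], H, W)
  cv$ch2 <- matrix(color[2], H, W)
  cv$ch3 <- matrix(color[3], H, W)
  cv
}

.canvas_array <- function(cv) {
  array(c(cv$ch1, cv$ch2, cv$ch3), dim = c(cv$H, cv$W, 3))
}

# Row-wise region fill: pixels with xl[row] <= x <= xr[row] (NA rows skipped).
.fill_rowband <- function(cv, xl, xr, color, shade = NULL) {
  .fill_rowband_cpp(cv$ch1, cv$ch2, cv$ch3, xl, xr, color,
                    if (is.null(shade)) numeric(0) else shade)
  invisible(NULL)
}

# Recolor the part of the row band lying above a per-column boundary
# y < ytop[col].
.fill_above <- function(cv, xl, xr, ytop, color) {
  .fill_above_cpp(cv$ch1, cv$ch2, cv$ch3, xl, xr, ytop, color)
  invisible(NULL)
}

# Anti-aliased blend of an alpha patch anchored at (r0, c0), 1-based.
.blend_patch <- function(cv, r0, c0, alpha, color) {
  .blend_patch_cpp(cv$ch1, cv$ch2, cv$ch3, as.integer(r0), as.integer(c0),
                   alpha, color)
  invisible(NULL)
}

# Stroke a polyline of (x, y) points with the given thickness and color.
.stroke <- function(cv, pts, thickness, color, alpha_max = 1) {
  H <- cv$H; W <- cv$W
  half <- thickness / 2
  for (i in seq_len(nrow(pts) - 1)) {
    x0 <- pts[i, 1]; y0 <- pts[i, 2]; x1 <- pts[i + 1, 1]; y1 <- pts[i + 1, 2]
    pad <- ceiling(half + 2)
    c0 <- max(1, floor(min(x0, x1)) - pad + 1)
    c1 <- min(W, ceiling(max(x0, x1)) + pad + 1)
    r0 <- max(1, floor(min(y0, y1)) - pad + 1)
    r1 <- min(H, ceiling(max(y0, y1)) + pad + 1)
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
    Xl <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    Yl <- matrix(ys, nrow = length(ys), ncol = length(xs))
    dx <- x1 - x0; dy <- y1 - y0
    len2 <- dx * dx + dy * dy
    if (len2 < 1e-9) {
      d <- sqrt((Xl - x0)^2 + (Yl - y0)^2)
    } else {
      t <- pmin(1, pmax(0, ((Xl - x0) * dx + (Yl - y0) * dy) / len2))
      d <- sqrt((Xl - (x0 + t * dx))^2 + (Yl - (y0 + t * dy))^2)
    }
    a <- pmin(pmax((half + 0.7 - d) / 1.4, 0), 1) * alpha_max
    .blend_patch(cv, r0, c0, a, color)
  }
  invisible(NULL)
}

.fill_ellipse_patch <- function(cv, cx, cy, rx, ry, color, alpha_max = 1) {
  H <- cv$H; W <- cv$W
  c0 <- max(1, floor(cx - rx)); c1 <- min(W, ceiling(cx + rx) + 1)
  r0 <- max(1, floor(cy - ry)); r1 <- min(H, ceiling(cy + ry) + 1)
  if (c0 > c1 || r0 > r1) return(invisible(NULL))
  xs <- (c0:c1) - 1; ys <- (r0:r1) - 1
  Xl <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Yl <- matrix(ys, nrow = length(ys), ncol = length(xs))
  q <- sqrt(((Xl - cx) / rx)^2 + ((Yl - cy) / ry)^2)
  a <- pmin(pmax((1 - q) * min(rx, ry) / 1.2, 0), 1) * alpha_max
  .blend_patch(cv, r0, c0, a, color)
  invisible(NULL)
}

.ellipse_pts <- function(cx, cy, rx, ry, n = 24, a0 = 0, a1 = 2 * pi) {
  th <- seq(a0, a1, length.out = n)
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

# Small circular arc passing exactly through (x, y); used for alar curves and
# tip highlights.
.arc_through <- function(cv, x, y, r, offx, offy, color, thickness = 2,
                         span = pi) {
  ccx <- x + offx; ccy <- y + offy
  ang <- atan2(y - ccy, x - ccx)
  pts <- .ellipse_pts(ccx, ccy, r, r, n = 14, a0 = ang - span / 2,
                      a1 = ang + span / 2)
  .stroke(cv, pts, thickness, color)
}

.render_frontal <- function(tpl, W, H, skin_tone) {
  p <- function(nm) unlist(tpl[tpl$name == nm, c("x", "y")], use.names = FALSE)
  cx <- W / 2
  s <- 0.55 + 0.30 * skin_tone
  skin <- s * c(1, 0.80, 0.66)
  dark <- function(f) skin * f
  Tr <- p("Tr"); G <- p("G"); N <- p("N"); Prn <- p("Prn"); Sn <- p("Sn")
  Phi <- p("Phi"); Ls <- p("Ls"); Stm <- p("Stm"); Li <- p("Li")
  Pg <- p("Pg"); Gn <- p("Gn"); Me <- p("Me")
  GoL <- p("GoL"); GoR <- p("GoR"); ChL <- p("ChL"); ChR <- p("ChR")
  AlL <- p("AlL"); AlR <- p("AlR"); ExL <- p("ExL"); ExR <- p("ExR")
  EnL <- p("EndL"); EnR <- p("EndR")

  cv <- .canvas(W, H)
  rows_all <- seq_len(H) - 1

  ## neck behind the face
  xl_neck <- ifelse(rows_all >= Me[2] - 0.02 * H, cx - 0.09 * W, NA)
  .fill_rowband(cv, xl_neck, xl_neck + 0.18 * W, skin * 0.88)

  ## head: upper half-ellipse over a jaw half-ellipse, meeting at Gonion level
  y_top <- Tr[2] - 0.07 * H
  y_go <- (GoL[2] + GoR[2]) / 2
  rxjL <- GoL[1] - cx; rxjR <- cx - GoR[1]
  rxuL <- rxjL + 0.02 * W; rxuR <- rxjR + 0.02 * W
  yy <- rows_all
  up <- yy >= y_top & yy < y_go
  low <- yy >= y_go & yy <= Me[2]
  fu <- sqrt(pmax(0, 1 - ((yy - y_go) / (y_go - y_top))^2))
  fl <- sqrt(pmax(0, 1 - ((yy - y_go) / (Me[2] - y_go))^2))
  xr_face <- ifelse(up, cx + rxuL * fu, ifelse(low, cx + rxjL * fl, NA))
  xl_face <- ifelse(up, cx - rxuR * fu, ifelse(low, cx - rxjR * fl, NA))
  shade <- 1 - 0.10 * pmax(0, (rows_all - y_top)) / H
  .fill_rowband(cv, xl_face, xr_face, skin, shade = shade)

  ## hair above the hairline parabola through Trichion
  khair <- 0.09 * H / (0.33 * W)^2
  hl <- Tr[2] + khair * ((seq_len(W) - 1) - cx)^2
  .fill_above(cv, xl_face, xr_face, hl, c(0.13, 0.10, 0.09))

  ## brows, glabellar groove, nasion crease
  for (sgn in c(-1, 1)) {
    bx0 <- cx + sgn * 0.07 * W; bx1 <- cx + sgn * 0.21 * W
    .stroke(cv, cbind(c(bx0, bx1), c(0.332 * H, 0.318 * H)),
            0.012 * H, c(0.20, 0.14, 0.11))
  }
  .stroke(cv, cbind(c(G[1], G[1]), c(G[2] - 0.02 * H, G[2] + 0.02 * H)),
          3, dark(0.85))
  .stroke(cv, cbind(c(N[1] - 0.022 * W, N[1] + 0.022 * W), c(N[2], N[2])),
          2.5, dark(0.80))

  ## eyes: outline through En/Ex, iris, pupil
  for (side in list(list(EnL, ExL), list(EnR, ExR))) {
    En <- side[[1]]; Ex <- side[[2]]
    ec <- (En[1] + Ex[1]) / 2; ey <- (En[2] + Ex[2]) / 2
    rx_e <- abs(Ex[1] - En[1]) / 2; ry_e <- 0.013 * H
    .fill_ellipse_patch(cv, ec, ey, rx_e, ry_e, c(0.97, 0.97, 0.95))
    .stroke(cv, .ellipse_pts(ec, ey, rx_e, ry_e, 28), 2.5,
            c(0.20, 0.15, 0.13))
    .fill_ellipse_patch(cv, ec, ey, ry_e * 0.85, ry_e * 0.85,
                        c(0.26, 0.17, 0.12))
    .fill_ellipse_patch(cv, ec, ey, ry_e * 0.35, ry_e * 0.35,
                        c(0.05, 0.05, 0.05))
  }

  ## nose: bridge, tip highlight through Prn, alar arcs through Al, base at Sn
  for (sgn in c(-1, 1)) {
    .stroke(cv, cbind(c(cx + sgn * 0.02 * W, cx + sgn * 0.028 * W),
                      c(N[2], Prn[2] - 0.02 * H)), 2, dark(0.90))
  }
  .arc_through(cv, Prn[1], Prn[2], 7, 0, -7, skin * 1.12, thickness = 2,
               span = 2 * pi)
  .arc_through(cv, AlL[1], AlL[2], 9, -9, 0, dark(0.78), 2.2)
  .arc_through(cv, AlR[1], AlR[2], 9, 9, 0, dark(0.78), 2.2)
  for (sgn in c(-1, 1))
    .fill_ellipse_patch(cv, cx + sgn * 0.035 * W, Sn[2] - 0.014 * H,
                        0.009 * W, 0.006 * H, c(0.25, 0.16, 0.13))
  .stroke(cv, cbind(c(Sn[1] - 0.02 * W, Sn[1] + 0.02 * W), c(Sn[2], Sn[2])),
          2.5, dark(0.80))

  ## philtrum groove through Phi
  .stroke(cv, cbind(c(Phi[1], Phi[1]), c(Sn[2] + 2, Ls[2] - 2)), 2,
          dark(0.88))

  ## lips: fill, upper border through Ls, mouth line through Ch/Stm, lower
  ## border through Li
  rx_lip <- abs(ChL[1] - ChR[1]) / 2 - 0.012 * W
  .fill_ellipse_patch(cv, cx, (Ls[2] + Li[2]) / 2, rx_lip,
                      (Li[2] - Ls[2]) / 2 + 2, c(0.72, 0.40, 0.36),
                      alpha_max = 0.9)
  .stroke(cv, cbind(
    c(ChR[1], cx - 0.05 * W, Ls[1], cx + 0.05 * W, ChL[1]),
    c(ChR[2], Ls[2] + 0.2 * (Stm[2] - Ls[2]), Ls[2],
      Ls[2] + 0.2 * (Stm[2] - Ls[2]), ChL[2])), 2.5, c(0.55, 0.25, 0.22))
  .stroke(cv, cbind(c(ChR[1], Stm[1], ChL[1]), c(ChR[2], Stm[2], ChL[2])),
          2.5, c(0.25, 0.12, 0.10))
  .stroke(cv, cbind(c(ChR[1] + 0.02 * W, Li[1], ChL[1] - 0.02 * W),
                    c(ChR[2] + 2, Li[2], ChL[2] + 2)), 2,
          c(0.50, 0.22, 0.20))

  ## chin creases through Pg and Gn (Me and Go lie on the silhouette)
  .stroke(cv, cbind(c(Pg[1] - 0.05 * W, Pg[1], Pg[1] + 0.05 * W),
                    c(Pg[2] + 0.012 * H, Pg[2], Pg[2] + 0.012 * H)),
          2.5, dark(0.82))
  .stroke(cv, cbind(c(Gn[1] - 0.04 * W, Gn[1], Gn[1] + 0.04 * W),
                    c(Gn[2] - 0.006 * H, Gn[2], Gn[2] - 0.006 * H)),
          2, dark(0.88))
  .canvas_array(cv)
}

.render_profile <- function(tpl, W, H, skin_tone) {
  p <- function(nm) unlist(tpl[tpl$name == nm, c("x", "y")], use.names = FALSE)
  s <- 0.55 + 0.30 * skin_tone
  skin <- s * c(1, 0.80, 0.66)
  dark <- function(f) skin * f
  Tr <- p("Tr"); G <- p("G"); N <- p("N"); Prn <- p("Prn"); Col <- p("Col")
  Al <- p("Al"); Sn <- p("Sn"); Phi <- p("Phi"); Ls <- p("Ls")
  Stm <- p("Stm"); Li <- p("Li"); Pg <- p("Pg"); Gn <- p("Gn")
  Me <- p("Me"); Go <- p("Go")

  cv <- .canvas(W, H)
  rows_all <- seq_len(H) - 1

  ## neck behind the head
  xl_neck <- ifelse(rows_all >= 0.78 * H, 0.34 * W, NA)
  .fill_rowband(cv, xl_neck, xl_neck + 0.22 * W, skin * 0.88)

  ## silhouette: x_right(y) piecewise-linear through the midsagittal landmarks
  y_top <- Tr[2] - 0.07 * H
  sil <- rbind(c(0.55 * W, y_top),
               Tr,
               c(0.705 * W, 0.21 * H),
               G, N,
               Prn, Col, Sn, Phi, Ls, Stm, Li,
               c(0.730 * W, (Li[2] + Pg[2]) / 2),
               Pg, Gn, Me)
  xr <- approx(sil[, 2], sil[, 1], xout = rows_all, rule = 1)$y
  ## back of head: ellipse arc, then a linear under-jaw boundary down to Me
  bc_y <- 0.40 * H; bry <- 0.38 * H; brx <- 0.30 * W; bcx <- 0.48 * W
  xl <- ifelse(abs(rows_all - bc_y) <= bry,
               bcx - brx * sqrt(pmax(0, 1 - ((rows_all - bc_y) / bry)^2)),
               NA)
  below <- rows_all > bc_y + bry & rows_all <= Me[2]
  xl[below] <- bcx + (rows_all[below] - (bc_y + bry)) /
    pmax(1, Me[2] - (bc_y + bry)) * (Me[1] - 0.06 * W - bcx)
  xl[rows_all > Me[2]] <- NA
  xr[rows_all > Me[2]] <- NA
  shade <- 1 - 0.10 * pmax(0, (rows_all - y_top)) / H
  .fill_rowband(cv, xl, xr, skin, shade = shade)

  ## hair: in front of Trichion the hairline sweeps up, behind it down
  xs <- seq_len(W) - 1
  hl <- ifelse(xs <= Tr[1], pmin(0.60 * H, Tr[2] + 0.9 * (Tr[1] - xs)),
               Tr[2] - 3 * (xs - Tr[1]))
  .fill_above(cv, xl, xr, hl, c(0.13, 0.10, 0.09))

  ## silhouette shadow stroke through every midsagittal landmark
  .stroke(cv, sil[-1, , drop = FALSE], 2.2, dark(0.75))

  ## jaw line through Gonion, up toward the ear
  .stroke(cv, rbind(Me, Go, c(0.44 * W, 0.60 * H)), 2.5, dark(0.80))

  ## ear
  .stroke(cv, .ellipse_pts(0.46 * W, 0.54 * H, 0.025 * W, 0.045 * H, 20), 2,
          dark(0.80))

  ## brow and eye
  .stroke(cv, cbind(c(0.60 * W, 0.70 * W), c(0.33 * H, 0.322 * H)),
          0.011 * H, c(0.20, 0.14, 0.11))
  ec <- 0.63 * W; ey <- 0.385 * H
  .fill_ellipse_patch(cv, ec, ey, 0.035 * W, 0.011 * H, c(0.97, 0.97, 0.95))
  .stroke(cv, .ellipse_pts(ec, ey, 0.035 * W, 0.011 * H, 22), 2,
          c(0.20, 0.15, 0.13))
  .fill_ellipse_patch(cv, ec + 0.012 * W, ey, 0.010 * H, 0.010 * H,
                      c(0.26, 0.17, 0.12))

  ## alar curve through Al, nostril
  .arc_through(cv, Al[1], Al[2], 9, -8, 3, dark(0.75), 2.2)
  .fill_ellipse_patch(cv, Al[1] - 0.012 * W, Al[2] + 0.010 * H, 0.007 * W,
                      0.005 * H, c(0.25, 0.16, 0.13))

  ## philtrum groove inside the silhouette
  .stroke(cv, cbind(c(Sn[1] - 0.006 * W, Phi[1] - 0.006 * W,
                      Ls[1] - 0.01 * W),
                    c(Sn[2] + 2, Phi[2], Ls[2] - 2)), 1.8, dark(0.85))

  ## lip color patches
  .fill_ellipse_patch(cv, Ls[1] - 0.015 * W, (Ls[2] + Stm[2]) / 2,
                      0.022 * W, (Stm[2] - Ls[2]) / 2 + 1,
                      c(0.72, 0.40, 0.36), alpha_max = 0.85)
  .fill_ellipse_patch(cv, Li[1] - 0.015 * W, (Stm[2] + Li[2]) / 2,
                      0.020 * W, (Li[2] - Stm[2]) / 2 + 1,
                      c(0.66, 0.34, 0.30), alpha_max = 0.85)
  .canvas_array(cv)
}
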