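# Independent brute-force geometric oracle in homogeneous line coordinates.
# A line through p and q is the cross product of their homogeneous
# embeddings; projections, intersections and distances follow from the
# (A, B, C) coefficients. This path shares no code with the package's
# anchored parametric-line implementation.

o_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

o_line <- function(p, q) o_cross(c(p, 1), c(q, 1))  # (A, B, C): Ax+By+C=0

o_project <- function(pt, p, q) {
  L <- o_line(p, q)
  r <- (L[1] * pt[1] + L[2] * pt[2] + L[3]) / (L[1]^2 + L[2]^2)
  c(pt[1] - r * L[1], pt[2] - r * L[2])
}

o_intersect <- function(p1, q1, p2, q2) {
  X <- o_cross(o_line(p1, q1), o_line(p2, q2))
  c(X[1] / X[3], X[2] / X[3])
}

o_point_line_dist <- function(pt, p, q) {
  L <- o_line(p, q)
  abs(L[1] * pt[1] + L[2] * pt[2] + L[3]) / sqrt(L[1]^2 + L[2]^2)
}

o_dist <- function(p, q) sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2)

o_angle_deg <- function(p1, q1, p2, q2) {
  a1 <- atan2(q1[2] - p1[2], q1[1] - p1[1])
  a2 <- atan2(q2[2] - p2[2], q2[1] - p2[1])
  d <- abs(a1 - a2) %% pi
  if (d > pi / 2) d <- pi - d
  d * 180 / pi
}

# from-scratch recomputation of the whole index panel from raw landmarks
oracle_panel <- function(lm) {
  P <- lm$points
  b_art <- o_dist(P$articular_superior_pole, P$articular_inferior_pole)
  T1 <- o_project(P$fibular_head_tip, P$shaft_mid_70, P$shaft_mid_110)
  T2 <- o_intersect(P$shaft_mid_70, P$shaft_mid_110,
                    P$joint_line_a, P$joint_line_b)
  list(
    IS = o_dist(P$patella_inferior_pole, P$tendon_insertion) /
      o_dist(P$patella_superior_pole, P$patella_inferior_pole),
    mIS = o_dist(P$articular_inferior_pole, P$tendon_insertion) / b_art,
    CD = o_dist(P$articular_inferior_pole, P$tibia_anterosuperior_margin) /
      b_art,
    BP = o_point_line_dist(P$articular_inferior_pole,
                           P$joint_line_a, P$joint_line_b) / b_art,
    AP = o_dist(P$articular_inferior_pole, T1) / b_art,
    jAP = o_dist(P$articular_inferior_pole, T2) / b_art,
    JLH = o_dist(T1, T2),
    PTS = 90 - o_angle_deg(P$joint_line_a, P$joint_line_b,
                           P$shaft_mid_70, P$shaft_mid_110))
}

# analytic ICC oracle: mean squares from R's own two-way ANOVA fit, ICC
# assembled from them independently of the package's direct-sum path
oracle_icc_21 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(aov(y ~ subj + rater, data = d))[["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

oracle_icc_31 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- anova(aov(y ~ subj + rater, data = d))[["Mean Sq"]]
  (ms[1] - ms[3]) / (ms[1] + (k - 1) * ms[3])
}

oracle_icc_11 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m), subj = factor(rep(seq_len(n), k)))
  ms <- anova(aov(y ~ subj, data = d))[["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}
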