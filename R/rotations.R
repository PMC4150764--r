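# Internal rigid-body helpers shared by the DNA geometry and disulfide code.
# Rotation matrices act on column vectors; frames are 3x3 matrices whose
# columns are the x, y, z axes expressed in global coordinates.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_x <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(1, 0, 0,
           0, cos(t), sin(t),
           0, -sin(t), cos(t)), 3, 3)
}

rot_y <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), 0, -sin(t),
           0, 1, 0,
           sin(t), 0, cos(t)), 3, 3)
}

rot_z <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), sin(t), 0,
           -sin(t), cos(t), 0,
           0, 0, 1), 3, 3)
}

# Rotation by theta (degrees) about an arbitrary unit axis (Rodrigues).
rot_axis <- function(axis, theta_deg) {
  u <- axis / sqrt(sum(axis^2))
  t <- deg2rad(theta_deg)
  ct <- cos(t); st <- sin(t)
  ux <- matrix(c(0, u[3], -u[2],
                 -u[3], 0, u[1],
                 u[2], -u[1], 0), 3, 3)
  diag(3) * ct + st * ux + (1 - ct) * (u %o% u)
}

vnorm <- function(v) sqrt(sum(v^2))
unitize <- function(v) v / vnorm(v)

# Signed angle (degrees) from a to b measured about unit axis n.
signed_angle <- function(a, b, n) {
  a <- unitize(a); b <- unitize(b)
  s <- sum(cross3(a, b) * n)
  c <- sum(a * b)
  rad2deg(atan2(s, c))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Nearest rotation matrix to M (special orthogonal Procrustes projection).
project_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Torsion angle (degrees, in (-180, 180]) defined by four points.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitize(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# --- Mid-step-triad step construction ----------------------------------------
#
# The relative rotation between consecutive base-pair frames is decomposed as
#   T = Rz(omega/2 - phi) . Ry(gamma) . Rz(omega/2 + phi)
# with gamma = sqrt(roll^2 + tilt^2), phi = atan2(tilt, roll), omega = twist;
# the displacement (shift, slide, rise) is expressed in the mid-step triad
#   M = Rz(omega/2 - phi) . Ry(gamma/2) . Rz(phi).
# This is the CEHS construction used by the 3DNA family of tools, with the
# standard axis semantics: roll about y, tilt about x, twist about z.

step_rotation <- function(tilt, roll, twist) {
  gamma <- sqrt(roll^2 + tilt^2)
  phi <- if (gamma < 1e-12) 0 else rad2deg(atan2(tilt, roll))
  rot_z(twist / 2 - phi) %*% rot_y(gamma) %*% rot_z(twist / 2 + phi)
}

step_midframe <- function(tilt, roll, twist) {
  gamma <- sqrt(roll^2 + tilt^2)
  phi <- if (gamma < 1e-12) 0 else rad2deg(atan2(tilt, roll))
  rot_z(twist / 2 - phi) %*% rot_y(gamma / 2) %*% rot_z(phi)
}

# Forward builder: frame2/origin2 from frame1/origin1 and the six parameters.
apply_step <- function(R1, o1, shift, slide, rise, tilt, roll, twist) {
  Tm <- step_rotation(tilt, roll, twist)
  Mm <- step_midframe(tilt, roll, twist)
  list(R = R1 %*% Tm, o = o1 + as.vector((R1 %*% Mm) %*% c(shift, slide, rise)))
}

# Inverse: extract the six parameters from two base-pair frames.
extract_step <- function(R1, o1, R2, o2) {
  z1 <- R1[, 3]; z2 <- R2[, 3]
  cg <- max(-1, min(1, sum(z1 * z2)))
  gamma <- rad2deg(acos(cg))
  if (gamma > 1e-9) {
    hinge <- unitize(cross3(z1, z2))
    R1p <- rot_axis(hinge, gamma / 2) %*% R1
    R2p <- rot_axis(hinge, -gamma / 2) %*% R2
  } else {
    hinge <- NULL
    R1p <- R1; R2p <- R2
  }
  zm <- unitize(R1p[, 3] + R2p[, 3])
  xm <- unitize(R1p[, 1] + R2p[, 1])
  ym <- unitize(cross3(zm, xm))
  xm <- cross3(ym, zm)
  Rm <- cbind(xm, ym, zm)
  twist <- signed_angle(R1p[, 1], R2p[, 1], zm)
  if (is.null(hinge)) {
    roll <- 0; tilt <- 0
  } else {
    phi <- signed_angle(hinge, ym, zm)
    roll <- gamma * cos(deg2rad(phi))
    tilt <- gamma * sin(deg2rad(phi))
  }
  disp <- as.vector(t(Rm) %*% (o2 - o1))
  list(shift = disp[1], slide = disp[2], rise = disp[3],
       tilt = tilt, roll = roll, twist = twist, midframe = Rm,
       midpoint = (o1 + o2) / 2)
}
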