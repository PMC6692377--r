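# shared oracles and small builders for the test surface

## central finite-difference check of analytic gradients for a given term set
fdGradientCheck <- function(state, box, mp, rs, flags, h = 2e-6,
                            particles = NULL) {
  r0 <- memrod:::.callForces(state, box, mp, rs, flags = flags)
  E <- function(st)
    sum(memrod:::.callForces(st, box, mp, rs, flags = flags)$energy)
  n <- nrow(state@pos)
  if (is.null(particles)) particles <- seq_len(n)
  worst <- c(pos = 0, orient = 0)
  for (i in particles) for (d in 1:3) {
    sp <- state; sp@pos[i, d] <- sp@pos[i, d] + h
    sm <- state; sm@pos[i, d] <- sm@pos[i, d] - h
    g <- (E(sp) - E(sm)) / (2 * h)
    ga <- -r0$force[i, d]
    if (abs(g) > 1e-8 || abs(ga) > 1e-8)
      worst["pos"] <- max(worst["pos"],
                          abs(g - ga) / max(1e-7, abs(g), abs(ga)))
    u <- state@orient[i, ]
    t1 <- c(u[2] - u[3], u[3] + u[1], -u[1] - u[2])
    t1 <- t1 - sum(t1 * u) * u
    nt <- sqrt(sum(t1^2))
    if (nt < 1e-6) next
    t1 <- t1 / nt
    sp <- state; up <- u + h * t1; sp@orient[i, ] <- up / sqrt(sum(up^2))
    sm <- state; um <- u - h * t1; sm@orient[i, ] <- um / sqrt(sum(um^2))
    g <- (E(sp) - E(sm)) / (2 * h)
    ga <- sum(r0$ugrad[i, ] * t1)
    if (abs(g) > 1e-8 || abs(ga) > 1e-8)
      worst["orient"] <- max(worst["orient"],
                             abs(g - ga) / max(1e-7, abs(g), abs(ga)))
  }
  worst
}

## a small mixed configuration: one (or two) rods plus loose membrane
## particles, overlap-free, with tangentially jittered orientations
mixedTestState <- function(seed = 7, chirality = "chiral", twoRods = TRUE,
                           epsilonSS = 3, jitter = 0.06) {
  set.seed(seed)
  rs <- rodSpec(cRod = 0.3, chirality = chirality, epsilonSS = epsilonSS)
  rod <- buildRod(rs)
  pos <- rod@pos + matrix(rnorm(nrow(rod@pos) * 3, 0, jitter), ncol = 3)
  orient <- rod@orient
  kind <- rod@kind; rodId <- rod@rodId; seg <- rod@segmentIndex
  side <- rod@hookSide
  if (twoRods) {
    rod2 <- buildRod(rs)
    p2 <- rod2@pos
    p2[, 2] <- p2[, 2] + 1.5
    p2[, 3] <- p2[, 3] + 0.4
    pos <- rbind(pos, p2)
    orient <- rbind(orient, rod2@orient)
    kind <- c(kind, rod2@kind); rodId <- c(rodId, rod2@rodId + 1L)
    seg <- c(seg, rod2@segmentIndex); side <- c(side, rod2@hookSide)
  }
  ## a band of membrane particles on a jittered grid, kept off the rods
  ## and off each other (well-conditioned for finite differences)
  gx <- rep(seq(-6, 6, by = 1.6), 2)
  gy <- rep(c(4.2, 5.8), each = length(gx) / 2)
  nmem <- length(gx)
  mpos <- cbind(gx, gy, 0) + matrix(runif(nmem * 3, -0.15, 0.15), nmem, 3)
  morient <- matrix(rnorm(nmem * 3), nmem, 3)
  morient <- morient / sqrt(rowSums(morient^2))
  pos <- rbind(pos, mpos); orient <- rbind(orient, morient)
  kind <- c(kind, rep("membrane", nmem))
  rodId <- c(rodId, rep(-1L, nmem)); seg <- c(seg, rep(-1L, nmem))
  side <- c(side, rep(0, nmem))
  for (i in seq_len(nrow(orient))) {
    u <- orient[i, ]; t1 <- rnorm(3); t1 <- t1 - sum(t1 * u) * u
    u2 <- u + jitter * t1
    orient[i, ] <- u2 / sqrt(sum(u2^2))
  }
  list(state = particleState(pos, orient, kind = kind,
                             rodId = as.integer(rodId),
                             segmentIndex = as.integer(seg),
                             hookSide = side),
       box = simulationBox(c(40, 40, 40), "flat"),
       rs = rs)
}

## Kabsch RMSD after optimal rigid superposition (reflection not allowed)
kabschRmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  s <- svd(t(Bc) %*% Ac)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Ac %*% R - Bc)^2)))
}

## brute-force connected components of rods from all backbone pair distances
bruteClusterSizes <- function(state, box, cutoff) {
  bb <- which(state@kind == "rod_backbone")
  rids <- sort(unique(state@rodId[bb]))
  nr <- length(rids)
  adj <- matrix(FALSE, nr, nr)
  dm <- memrod:::.pairDistances(state@pos[bb, , drop = FALSE],
                                state@pos[bb, , drop = FALSE], box)
  ri <- match(state@rodId[bb], rids)
  for (a in seq_len(nr)) for (b in seq_len(nr))
    adj[a, b] <- any(dm[ri == a, ri == b] < cutoff)
  seen <- rep(FALSE, nr)
  sizes <- integer(0)
  for (s0 in seq_len(nr)) {
    if (seen[s0]) next
    q <- s0; seen[s0] <- TRUE; comp <- 0
    while (length(q)) {
      v <- q[1]; q <- q[-1]; comp <- comp + 1
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      q <- c(q, nb)
    }
    sizes <- c(sizes, comp)
  }
  sizes
}

## random rod scatter (no membrane) for cluster statistics
randomRodScatter <- function(nRods, seed, boxL = 40, clump = 8) {
  set.seed(seed)
  rs <- rodSpec(cRod = 0.25, chirality = "achiral_plain")
  rod <- buildRod(rs)
  pos <- NULL; rodId <- integer(0); seg <- integer(0)
  for (r in seq_len(nRods)) {
    centre <- runif(3, 0, clump)
    ang <- runif(1, 0, 2 * pi)
    Rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
    p <- rod@pos %*% Rz + matrix(centre, nrow(rod@pos), 3, byrow = TRUE)
    pos <- rbind(pos, p)
    rodId <- c(rodId, rep(r - 1L, nrow(p)))
    seg <- c(seg, rod@segmentIndex)
  }
  orient <- matrix(rep(c(0, 0, 1), each = nrow(pos)), ncol = 3)
  list(state = particleState(pos, orient, kind = "rod_backbone",
                             rodId = as.integer(rodId),
                             segmentIndex = as.integer(seg)),
       box = simulationBox(c(boxL, boxL, boxL), "flat"))
}

## documented w_cv formula, recomputed independently of the C implementation
wcvOracle <- function(r, mp) {
  s <- r / mp@rCc
  ifelse(s >= 1, 0, mp@alphaCv * exp((r / mp@rGa)^2 / (s^12 - 1)))
}
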