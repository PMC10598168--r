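## Independent plain-R oracles used to freeze expected values.
## These deliberately share no code with the package internals.

## brute-force ray/triangle intersection (Moeller-Trumbore), one ray
oracleRayTri <- function(o, d, v0, v1, v2) {
  e1 <- v1 - v0; e2 <- v2 - v0
  p <- c(d[2] * e2[3] - d[3] * e2[2],
         d[3] * e2[1] - d[1] * e2[3],
         d[1] * e2[2] - d[2] * e2[1])
  det <- sum(e1 * p)
  if (abs(det) < 1e-12) return(NA_real_)
  tv <- o - v0
  u <- sum(tv * p) / det
  if (u < -1e-9 || u > 1 + 1e-9) return(NA_real_)
  q <- c(tv[2] * e1[3] - tv[3] * e1[2],
         tv[3] * e1[1] - tv[1] * e1[3],
         tv[1] * e1[2] - tv[2] * e1[1])
  v <- sum(d * q) / det
  if (v < -1e-9 || u + v > 1 + 1e-9) return(NA_real_)
  sum(e2 * q) / det
}

## first positive hit of a ray against a whole mesh
oracleRayMesh <- function(o, d, mesh, tMax = Inf) {
  V <- vertices(mesh); F <- faces(mesh)
  best <- Inf
  for (f in seq_len(nrow(F))) {
    t <- oracleRayTri(o, d, V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ])
    if (!is.na(t) && t > 1e-7 && t <= tMax && t < best) best <- t
  }
  if (is.finite(best)) best else NA_real_
}

## brute-force connected-component labelling over the face adjacency graph
## (faces adjacent iff they share an edge); returns per-face component id
oracleFaceComponents <- function(F) {
  nf <- nrow(F)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
  edges <- list()
  for (f in seq_len(nf)) {
    for (pr in list(c(1, 2), c(2, 3), c(3, 1))) {
      k <- ekey(F[f, pr[1]], F[f, pr[2]])
      edges[[k]] <- c(edges[[k]], f)
    }
  }
  comp <- seq_len(nf)
  repeat {
    changed <- FALSE
    for (fs in edges) {
      if (length(fs) >= 2) {
        m <- min(comp[fs])
        if (any(comp[fs] != m)) { comp[fs] <- m; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

## one masked umbrella smoothing step by explicit double loop
oracleUmbrellaStep <- function(values, mask, F, weight) {
  n <- length(values)
  nbr <- vector("list", n)
  for (f in seq_len(nrow(F))) {
    tri <- F[f, ]
    for (a in tri) for (b in tri) if (a != b)
      nbr[[a]] <- union(nbr[[a]], b)
  }
  out <- values
  for (i in seq_len(n)) {
    if (!mask[i]) next
    nb <- nbr[[i]][mask[nbr[[i]]]]
    if (length(nb))
      out[i] <- (1 - weight) * values[i] + weight * mean(values[nb])
  }
  out
}

## dense 2-D grid search over the two edge positions at fixed nuisance
## parameters; independent check of blur-model identifiability
oracleEdgeGridSearch <- function(t, y, b, A1, A2, s, eGrid) {
  best <- c(NA, NA); bestSse <- Inf
  for (e1 in eGrid) {
    for (e2 in eGrid[eGrid >= e1]) {
      pred <- b + (A1 - b) * pnorm((e1 - t) / s) + (A2 - b) * pnorm((t - e2) / s)
      sse <- sum((y - pred)^2)
      if (sse < bestSse) { bestSse <- sse; best <- c(e1, e2) }
    }
  }
  best
}

## synthesize a profile directly from the two-edge blur model
modelProfile <- function(t, b, A1, A2, e1, e2, s, noiseSd = 0, seed = NULL) {
  y <- b + (A1 - b) * pnorm((e1 - t) / s) + (A2 - b) * pnorm((t - e2) / s)
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(t), 0, noiseSd)
  }
  Profile(t, y)
}

## two right triangles with areas 1 and 3 sharing an edge (patch fixture)
twoTrianglePatch <- function() {
  v <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0), c(2, 3, 0))
  f <- rbind(c(1, 2, 3), c(2, 4, 3))
  mesh <- SurfaceMesh(v, f)
  JointPatch(mesh, 1:4, "two-tri")
}
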