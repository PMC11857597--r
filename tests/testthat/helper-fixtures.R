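# Shared fixtures and independent oracles.

# Small scene: default layout rendered at the default 1024 x 768.
make_scene <- function(seed = 1L, noise_sigma = 5, mode = "qc", ...) {
  lay <- default_layout()
  scene_config(layout = lay,
               amplitudes = default_amplitudes(lay, mode = mode),
               noise_sigma = noise_sigma, seed = seed, ...)
}

# Brute-force flood-fill component labelling (recursive stack walk,
# one pixel at a time) -- independent of the package's frontier BFS.
oracle_label <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (connectivity == 4L) {
    nb <- cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else {
    nb <- cbind(rep(c(-1L, 0L, 1L), 3), rep(c(-1L, 0L, 1L), each = 3))
    nb <- nb[!(nb[, 1] == 0L & nb[, 2] == 0L), ]
  }
  id <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    id <- id + 1L
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- id
      r <- ((p - 1L) %% H) + 1L
      c <- ((p - 1L) %/% H) + 1L
      for (k in seq_len(nrow(nb))) {
        rr <- r + nb[k, 1]; cc <- c + nb[k, 2]
        if (rr >= 1L && rr <= H && cc >= 1L && cc <= W &&
            mask[rr, cc] && lab[rr, cc] == 0L)
          stack <- c(stack, (cc - 1L) * H + rr)
      }
    }
  }
  lab
}

# Component labelings are equal up to renaming of ids.
same_labeling <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  length(unique(key)) == length(unique(a[fg])) &&
    length(unique(key)) == length(unique(b[fg]))
}

# Brute-force AUC: count positive-negative pairs directly.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Minimal GenePix ATF/GPR writer for reader tests.
write_gpr_fixture <- function(path, rows,
                              headers = c("Type=GenePix Results 3",
                                          "Wavelengths=532")) {
  cols <- c("Block", "Row", "Column", "Name",
            "F532 Median", "B532 Median")
  lines <- c("ATF\t1.0",
             sprintf("%d\t%d", length(headers), length(cols)),
             sprintf("\"%s\"", headers),
             paste(sprintf("\"%s\"", cols), collapse = "\t"),
             vapply(seq_len(nrow(rows)), function(i)
               paste(c(rows$Block[i], rows$Row[i], rows$Column[i],
                       sprintf("\"%s\"", rows$Name[i]),
                       rows$F[i], rows$B[i]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  path
}

fourpl_truth <- function(x, a, b, c, d) d + (a - d) / (1 + (x / c)^b)
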