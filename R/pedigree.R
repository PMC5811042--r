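#' Pedigree objects
#'
#' A pedigree is a set of (animal, sire, dam) triples; \code{"0"}, \code{""}
#' and \code{NA} denote an unknown parent.  Ids are opaque strings.  Parents
#' that never appear as animals are auto-added as founders (standard handling
#' of incomplete herd pedigrees), and the result is stored topologically
#' ordered: every parent precedes its offspring.  An animal that is its own
#' ancestor is a hard error.
#'
#' @param animal,sire,dam Character (or coercible) vectors of equal length.
#' @return An object of class \code{pedigree}: a list with \code{id}
#'   (character), \code{sire}, \code{dam} (integer indices into \code{id},
#'   \code{NA} = unknown) and \code{generation} (0 for founders).
#' @examples
#' p <- pedigree(c("1", "2", "3"), c("0", "0", "1"), c("0", "0", "2"))
#' amatrix(p)
#' @export
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  stopifnot(length(animal) == length(sire), length(animal) == length(dam))
  unknown <- function(x) is.na(x) | x == "0" | x == ""
  sire[unknown(sire)] <- NA_character_
  dam[unknown(dam)] <- NA_character_
  if (anyDuplicated(animal))
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  if (any(!is.na(sire) & sire == animal) || any(!is.na(dam) & dam == animal))
    stop("cycle in pedigree: animal ",
         animal[which(sire == animal | dam == animal)[1L]],
         " is its own parent")

  ## closure: undeclared parents become founders
  extra <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(extra)) {
    animal <- c(extra, animal)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
  }

  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)

  ## Kahn topological sort; leftover nodes witness a cycle
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order <- integer(0)
  gen <- integer(n)
  queue <- which(indeg == 0L)
  gen[queue] <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    for (w in kids[[v]]) {
      gen[w] <- max(gen[w], gen[v] + 1L)
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < n) {
    cyc <- setdiff(seq_len(n), order)
    stop("cycle in pedigree: animal ", animal[cyc[1L]], " is its own ancestor")
  }

  perm <- order
  inv <- integer(n); inv[perm] <- seq_len(n)
  remap <- function(ix) ifelse(is.na(ix), NA_integer_, inv[ix])
  structure(
    list(id = animal[perm],
         sire = remap(si[perm]),
         dam = remap(di[perm]),
         generation = gen[perm]),
    class = "pedigree"
  )
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("Pedigree: %d animals (%d founders), %d generation level(s)\n",
              length(x$id), nf, max(x$generation) + 1L))
  invisible(x)
}

#' @export
length.pedigree <- function(x) length(x$id)

#' @export
as.data.frame.pedigree <- function(x, ...) {
  data.frame(animal = x$id,
             sire = ifelse(is.na(x$sire), "0", x$id[x$sire]),
             dam = ifelse(is.na(x$dam), "0", x$id[x$dam]),
             generation = x$generation,
             stringsAsFactors = FALSE)
}

#' Read / write a 3-column pedigree file
#'
#' Plain-text animal/sire/dam triples, whitespace- or comma-separated, with
#' \code{0} for an unknown parent; an optional header line
#' (\code{animal sire dam}) is detected and skipped.
#'
#' @param path File path.
#' @return \code{read_pedigree}: a \code{\link{pedigree}}.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty pedigree file: ", path)
  split1 <- function(s) strsplit(trimws(s), "[,[:space:]]+")[[1L]]
  first <- split1(lines[1L])
  if (any(tolower(first) %in% c("animal", "sire", "dam", "animal_id")))
    lines <- lines[-1L]
  toks <- lapply(lines, split1)
  bad <- which(vapply(toks, length, 1L) < 3L)
  if (length(bad))
    stop("pedigree line(s) with fewer than 3 fields: line ", bad[1L])
  m <- t(vapply(toks, function(x) x[1:3], character(3L)))
  pedigree(m[, 1L], m[, 2L], m[, 3L])
}

#' @rdname read_pedigree
#' @param ped A \code{\link{pedigree}}.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  df <- as.data.frame(ped)
  utils::write.table(df[, c("animal", "sire", "dam")], path,
                     quote = FALSE, row.names = FALSE, sep = " ",
                     eol = "\n")
  invisible(path)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes F for every animal by accumulating \eqn{a_{ii} = \sum_j L_{ij}^2
#' D_j} over the animal's ancestors, where \eqn{D_j} is the Mendelian
#' sampling variance scale \eqn{0.5 - 0.25 (F_{s(j)} + F_{d(j)})} (with the
#' usual \eqn{F = -1} convention for unknown parents).  Exact and O(n *
#' ancestry depth), no relationship matrix formed.
#'
#' @param ped A \code{\link{pedigree}}.
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  s <- ped$sire; d <- ped$dam
  f <- numeric(n)
  Fpar <- function(p) if (is.na(p)) -1 else f[p]
  L <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(s[i]) || is.na(d[i])) { f[i] <- 0; next }
    an <- i
    L[i] <- 1
    aii <- 0
    while (length(an)) {
      j <- max(an)
      an <- an[an != j]
      Dj <- 0.5 - 0.25 * (Fpar(s[j]) + Fpar(d[j]))
      aii <- aii + L[j]^2 * Dj
      if (!is.na(s[j])) {
        if (!(s[j] %in% an)) an <- c(an, s[j])
        L[s[j]] <- L[s[j]] + 0.5 * L[j]
      }
      if (!is.na(d[j])) {
        if (!(d[j] %in% an)) an <- c(an, d[j])
        L[d[j]] <- L[d[j]] + 0.5 * L[j]
      }
      L[j] <- 0
    }
    f[i] <- aii - 1
  }
  names(f) <- ped$id
  f
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense additive relationship matrix A: \eqn{a_{ii} = 1 + F_i} and
#' \eqn{a_{ij} = 0.5 (a_{j,s(i)} + a_{j,d(i)})}.  Intended for testing and
#' small pedigrees; the mixed-model solver consumes \code{\link{ainverse}}
#' directly and never materialises A.
#'
#' @param ped A \code{\link{pedigree}}.
#' @return Dense symmetric matrix with animal ids as dimnames.
#' @export
amatrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  s <- ped$sire; d <- ped$dam
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(si)) numeric(i - 1L) else A[j, si]
      ad_ <- if (is.na(di)) numeric(i - 1L) else A[j, di]
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (is.na(si) || is.na(di)) 0 else 0.5 * A[si, di]
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding from \code{\link{inbreeding}}
#' (Meuwissen-Luo): each animal contributes \eqn{\alpha_i = 1 / D_i} to at
#' most 9 entries over (animal, sire, dam) pairs, where \eqn{D_i} is the
#' Mendelian sampling variance scale.  Never forms A.
#'
#' @param ped A \code{\link{pedigree}}.
#' @return A sparse symmetric \code{\link[Matrix]{dsCMatrix}} with animal ids
#'   as dimnames.
#' @export
ainverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- length(ped$id)
  s <- ped$sire; d <- ped$dam
  f <- inbreeding(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    fs <- if (is.na(s[i])) -1 else f[s[i]]
    fd <- if (is.na(d[i])) -1 else f[d[i]]
    alpha <- 1 / (0.5 - 0.25 * (fs + fd))
    push(i, i, alpha)
    for (p in c(s[i], d[i])) {
      if (!is.na(p)) {
        push(i, p, -alpha / 2)
        push(p, i, -alpha / 2)
      }
    }
    kn <- c(s[i], d[i]); kn <- kn[!is.na(kn)]
    if (length(kn)) {
      for (p in kn) for (q in kn) push(p, q, alpha / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}

#' Export the lower triangle of A-inverse as row/col/value triplets
#'
#' @param ped A \code{\link{pedigree}}.
#' @param path Output CSV path (columns \code{row, col, value}, 1-based,
#'   lower triangle).
#' @export
write_ainverse_triplets <- function(ped, path) {
  Ainv <- ainverse(ped)
  tr <- Matrix::mat2triplet(Matrix::tril(Ainv))
  df <- data.frame(row = tr$i, col = tr$j, value = tr$x)
  df <- df[order(df$row, df$col), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
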