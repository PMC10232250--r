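# Banded semi-global alignment on the linearized graph. The table D has one
# column per gstring position and one row per read position; the seed cell
# pins read position i* to gstring position j*, splitting the problem into an
# independent forward part (r[i*, |r|] vs G^ from j* rightwards) and backward
# part (r[1, i*-1] vs G^ ending left of j*). Columns are computed left to
# right (resp. right to left) with the standard match/mismatch/insertion/
# deletion cases on base columns and three extra cases on syntax columns:
# at '(' and '|' the column is a copy of the column immediately preceding the
# ED symbol, at ')' it is the element-wise minimum over the columns ending
# each alternative, and at '#' the computation branches to every successor
# reachable over a jump edge, each branch inheriting the current column.
# Cells larger than the error bound d (and, with pruning, not smaller than
# the best complete alignment found so far) are discarded; a branch dies when
# its whole column is discarded, which also bounds the depth of cyclic
# branching.

.dp_engine <- function(graph, seg, start_pos, init_vec, d, dir = 1L,
                       prune = TRUE, pin_first = FALSE, max_jumps = 500L) {
  m <- length(seg)
  n <- graph$n
  type <- graph$meta$type
  chars <- graph$chars
  openc <- if (dir == 1L) "open" else "close"
  closec <- if (dir == 1L) "close" else "open"
  S <- length(graph$sep_pos)

  env <- new.env(parent = emptyenv())
  env$cols <- vector("list", 64L)
  env$ncol <- 0L
  env$best <- Inf
  env$best_col <- NA_integer_
  env$ev_j <- integer(0)
  env$ev_val <- numeric(0)
  add_col <- function(rec) {
    env$ncol <- env$ncol + 1L
    if (env$ncol > length(env$cols)) {
      env$cols <- c(env$cols, vector("list", length(env$cols)))
    }
    env$cols[[env$ncol]] <- rec
    env$ncol
  }
  init_id <- add_col(list(type = "init", j = NA_integer_, parent = 0L,
                          vec = init_vec))
  if (is.finite(init_vec[m + 1L]) && init_vec[m + 1L] <= d) {
    env$best <- init_vec[m + 1L]
    env$best_col <- init_id
  }
  idxv <- 0:m

  jump_conts <- function(pos_out_left, s) {
    # continuation positions over jump edges
    if (dir == 1L) {
      targets <- graph$fwd[[as.character(s)]]
      if (is.null(targets)) return(integer(0))
      sort(vapply(targets, function(t) if (t == 0L) 1L else graph$sep_pos[t] + 1L,
                  integer(1)))
    } else {
      keys <- graph$bwd[[as.character(s)]]
      if (is.null(keys)) return(integer(0))
      sort(vapply(keys, function(a) if (a <= S) graph$sep_pos[a] - 1L else n,
                  integer(1)))
    }
  }

  run <- function(pos, parent_id, jumps, first) {
    open_pre <- NA_integer_
    acc <- integer(0)
    repeat {
      if (pos < 1L || pos > n) {
        # past the end of the gstring: the last/first node may still have
        # jump edges (key S+1 forward, target 0 backward)
        s <- if (dir == 1L) S + 1L else 0L
        conts <- jump_conts(pos, s)
        if (length(conts) > 0L && jumps < max_jumps) {
          for (cont in conts) run(cont, parent_id, jumps + 1L, FALSE)
        }
        return(invisible(NULL))
      }
      tp <- type[pos]
      if (tp == "base") {
        c0 <- chars[pos]
        P <- env$cols[[parent_id]]$vec
        subv <- if (c0 == "N") numeric(m) else as.numeric(seg != c0)
        cand <- numeric(m + 1L)
        cand[1L] <- P[1L] + 1
        if (m > 0L) {
          cand[2:(m + 1L)] <- pmin(P[1:m] + subv, P[2:(m + 1L)] + 1)
        }
        vec <- idxv + cummin(cand - idxv)   # within-column insertions
        if (first) {
          vec[1L] <- Inf                    # r[i*] must align with G^[j*]
          first <- FALSE
        }
        lim <- if (prune) min(d, env$best - 1) else d
        vec[vec > lim] <- Inf
        if (all(is.infinite(vec)) && is.na(graph$meta$open_pos[pos])) {
          # dead column outside any ED symbol: the branch cannot recover.
          # Inside a symbol the scan must go on, because other alternatives
          # (cached in the accumulator) may still be alive.
          return(invisible(NULL))
        }
        id <- add_col(list(type = "base", j = pos, parent = parent_id,
                           vec = vec, char = c0))
        fin <- vec[m + 1L]
        if (is.finite(fin)) {
          env$ev_j <- c(env$ev_j, pos)
          env$ev_val <- c(env$ev_val, fin)
          if (fin < env$best) { env$best <- fin; env$best_col <- id }
        }
        parent_id <- id
        pos <- pos + dir
      } else if (tp == openc) {
        open_pre <- parent_id
        id <- add_col(list(type = "copy", j = pos, parent = open_pre,
                           vec = env$cols[[open_pre]]$vec))
        parent_id <- id
        pos <- pos + dir
      } else if (tp == "pipe") {
        if (is.na(open_pre)) {
          # the scan started inside this symbol (seed within an alternative):
          # the walk is committed to that alternative, so the remaining
          # alternatives are skipped and the scan resumes after the symbol
          pos <- if (dir == 1L) graph$meta$close_pos[pos] + 1L else
            graph$meta$open_pos[pos] - 1L
          next
        }
        acc <- c(acc, parent_id)
        id <- add_col(list(type = "copy", j = pos, parent = open_pre,
                           vec = env$cols[[open_pre]]$vec))
        parent_id <- id
        pos <- pos + dir
      } else if (tp == closec) {
        acc <- c(acc, parent_id)
        vec <- Reduce(pmin, lapply(acc, function(a) env$cols[[a]]$vec))
        id <- add_col(list(type = "min", j = pos, parent = acc[1L],
                           srcs = acc, vec = vec))
        parent_id <- id
        open_pre <- NA_integer_
        acc <- integer(0)
        pos <- pos + dir
      } else { # separator
        s <- graph$sep_at[pos]
        conts <- jump_conts(pos, s)
        if (length(conts) > 0L && jumps < max_jumps) {
          for (cont in conts) {
            id <- add_col(list(type = "jump", j = pos, parent = parent_id,
                               vec = env$cols[[parent_id]]$vec))
            run(cont, id, jumps + 1L, FALSE)
          }
        }
        return(invisible(NULL))
      }
    }
  }
  run(start_pos, init_id, 0L, pin_first)
  list(best = env$best, best_col = env$best_col,
       cols = env$cols[seq_len(env$ncol)],
       events = data.frame(j = env$ev_j, value = env$ev_val))
}

# Walk the column DAG back from a completion cell to the init column,
# emitting edit operations ("=", "X", "I", "D") in reverse order of the scan.
.dp_traceback <- function(cols, best_col, seg) {
  m <- length(seg)
  i <- m
  col <- best_col
  ops <- character(0)
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 100000L) stop("traceback guard tripped", call. = FALSE)
    rec <- cols[[col]]
    if (rec$type == "init") {
      if (i > 0L) ops <- c(ops, rep("I", i))
      break
    }
    if (rec$type == "base") {
      P <- cols[[rec$parent]]$vec
      v <- rec$vec[i + 1L]
      if (i >= 1L) {
        sub <- if (rec$char == "N") 0 else as.numeric(seg[i] != rec$char)
        if (is.finite(P[i]) && v == P[i] + sub) {
          ops <- c(ops, if (sub == 0) "=" else "X")
          i <- i - 1L; col <- rec$parent; next
        }
        if (is.finite(rec$vec[i]) && v == rec$vec[i] + 1) {
          ops <- c(ops, "I"); i <- i - 1L; next
        }
      }
      if (is.finite(P[i + 1L]) && v == P[i + 1L] + 1) {
        ops <- c(ops, "D"); col <- rec$parent; next
      }
      stop("inconsistent alignment table during traceback", call. = FALSE)
    }
    if (rec$type == "min") {
      hit <- NULL
      for (s in rec$srcs) {
        if (cols[[s]]$vec[i + 1L] == rec$vec[i + 1L]) { hit <- s; break }
      }
      if (is.null(hit)) stop("traceback failed at ')' column", call. = FALSE)
      col <- hit
      next
    }
    col <- rec$parent  # copy / jump: same row, no operation
  }
  ops
}

#' Forward semi-global alignment from a seed
#'
#' Aligns the read suffix `r[i_star, |r|]` against the graph starting at
#' `j_star`, enforcing that `r[i_star]` is aligned with `G^[j_star]`, with
#' unit-cost edit operations and error bound `d`. `N` in the graph matches
#' any read base. Branches over jump edges at every separator; with
#' `prune = TRUE` cells not smaller than the best complete alignment found so
#' far are discarded (the optimum is unaffected).
#'
#' @param read Read sequence (string over `A,C,G,T`).
#' @param graph An `eds_graph`.
#' @param i_star,j_star Seed: read position / gstring position (a base).
#' @param d Maximum number of errors.
#' @param prune Keep only cells that can still beat the current best.
#' @return A list: `distance` (Inf when the bound is exceeded), `hi` (last
#'   gstring position of the alignment), `ops` (edit script from the seed
#'   onward), and `events`, a data.frame with the value of the final read row
#'   observed at each completed base column (instrumentation of the column
#'   scan).
#' @export
align_forward <- function(read, graph, i_star, j_star, d, prune = TRUE) {
  stopifnot(inherits(graph, "eds_graph"))
  rchars <- strsplit(read, "", fixed = TRUE)[[1]]
  L <- length(rchars)
  stopifnot(i_star >= 1L, i_star <= L, j_star >= 1L, j_star <= graph$n)
  if (graph$meta$type[j_star] != "base")
    stop("j_star must address a base", call. = FALSE)
  seg <- rchars[i_star:L]
  m <- length(seg)
  init <- c(0, rep(Inf, m))
  res <- .dp_engine(graph, seg, j_star, init, d, dir = 1L,
                    prune = prune, pin_first = TRUE)
  if (!is.finite(res$best)) {
    return(list(distance = Inf, hi = NA_integer_, ops = NULL,
                events = res$events))
  }
  ops <- rev(.dp_traceback(res$cols, res$best_col, seg))
  hi <- res$cols[[res$best_col]]$j
  list(distance = res$best, hi = hi, ops = ops, events = res$events)
}

#' Backward semi-global alignment from a seed
#'
#' Mirror of [align_forward()]: aligns the read prefix `r[1, i_star-1]`
#' against the graph ending immediately left of `j_star`, traversing
#' separators via the inverted adjacency list. A forward distance `d'` leaves
#' a budget of `d - d'` for this part.
#'
#' @inheritParams align_forward
#' @param d_remaining Remaining error budget.
#' @return A list: `distance`, `lo` (first gstring position of the full
#'   alignment; `j_star` when the prefix is empty or aligned entirely by
#'   insertions), `ops` (edit script left-to-right up to the seed).
#' @export
align_backward <- function(read, graph, i_star, j_star, d_remaining,
                           prune = TRUE) {
  stopifnot(inherits(graph, "eds_graph"))
  rchars <- strsplit(read, "", fixed = TRUE)[[1]]
  stopifnot(i_star >= 1L, i_star <= length(rchars))
  m <- i_star - 1L
  if (m == 0L) {
    return(list(distance = 0, lo = j_star, ops = character(0)))
  }
  seg <- rev(rchars[seq_len(m)])
  init <- as.numeric(0:m)
  res <- .dp_engine(graph, seg, j_star - 1L, init, d_remaining, dir = -1L,
                    prune = prune, pin_first = FALSE)
  if (!is.finite(res$best)) {
    return(list(distance = Inf, lo = NA_integer_, ops = NULL))
  }
  rec <- res$cols[[res$best_col]]
  lo <- if (rec$type == "init") j_star else rec$j
  ops <- if (rec$type == "init") rep("I", m) else
    .dp_traceback(res$cols, res$best_col, seg)
  list(distance = res$best, lo = lo, ops = ops)
}
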