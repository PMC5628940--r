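# Deterministic gridworld MDP: geometry, actions, transitions, rewards,
# terminal bookkeeping, and a BFS shortest-path oracle.

#' Action set
#'
#' Actions are encoded as integers `1:5` in the fixed order N, E, S, W,
#' collect. The four cardinal moves are deterministic; `collect` exists only
#' in rewarded cells, yields that cell's reward and ends the episode
#' (transition to the absorbing terminal pseudo-state).
#'
#' @format An integer vector of length 5 with names `N`, `E`, `S`, `W`,
#'   `collect`.
#' @export
ACTIONS <- c(N = 1L, E = 2L, S = 3L, W = 4L, collect = 5L)

# displacement of each cardinal action in (dx, dy), y growing downwards
.ACTION_DELTA <- matrix(c(0L, -1L,   # N
                          1L,  0L,   # E
                          0L,  1L,   # S
                          -1L, 0L),  # W
                        ncol = 2L, byrow = TRUE)

.MARKER_LABELS <- c(S = "S", `1` = "S1", `2` = "S2",
                    R = "R", r = "R1", Q = "R2", B = "B")

#' Parse an ASCII maze map into a gridworld
#'
#' The map dialect uses one character per cell: `#` wall, `.` open cell,
#' `S`/`1`/`2` start markers (labels `S`, `S1`, `S2`), `R`/`r`/`Q` reward
#' markers (labels `R`, `R1`, `R2`), and `B` a future-barrier marker (open
#' until a protocol inserts a wall there). Rows are newline-separated and must
#' be equal length; trailing whitespace is an error. Marker cells are open.
#' Reward-marker cells are terminal "reward sites" from the outset: their only
#' action is `collect` and their magnitude starts at 0, until a task protocol
#' raises it via [set_reward()]. All other cells carry no reward.
#'
#' Coordinates are 0-based `(x, y)` with origin at the top-left; open cells
#' are assigned state indices `1..S` in row-major order. The index assignment
#' is permanent: a cell later converted to a wall by [insert_wall()] keeps its
#' index (with an empty action set), so agents' matrices keep fixed dimensions
#' across transition-revaluation manipulations.
#'
#' @param text A single string containing the map, or a character vector of
#'   rows.
#' @return An object of class `gridworld`.
#' @examples
#' w <- parse_grid_map("S.R")
#' w$n_states
#' available_actions(w, 1L)
#' @export
parse_grid_map <- function(text) {
  rows <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  rows <- rows[nzchar(rows)]
  if (length(rows) == 0L) stop("empty map")
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged map: row %d has %d characters, expected %d",
                 bad, widths[bad], widths[1]))
  }
  if (any(grepl("[ \t]$", rows))) stop("trailing whitespace in map row")
  height <- length(rows)
  width <- widths[1]
  cells <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  known <- c("#", ".", names(.MARKER_LABELS))
  bad <- which(matrix(!(cells %in% known), nrow(cells)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("unknown map character '%s' at line %d, column %d",
                 cells[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))
  }

  open_mask <- cells != "#"
  n_states <- sum(open_mask)
  if (n_states == 0L) stop("map has no open cells")
  state_at <- matrix(NA_integer_, height, width)
  idx <- 0L
  coords <- matrix(0L, n_states, 2L, dimnames = list(NULL, c("x", "y")))
  for (r in seq_len(height)) {
    for (c in seq_len(width)) {
      if (open_mask[r, c]) {
        idx <- idx + 1L
        state_at[r, c] <- idx
        coords[idx, ] <- c(c - 1L, r - 1L)
      }
    }
  }

  labels <- integer(0)
  for (marker in names(.MARKER_LABELS)) {
    hits <- which(cells == marker, arr.ind = TRUE)
    if (nrow(hits) > 1L) {
      stop(sprintf("duplicate label '%s' at line %d, column %d",
                   marker, hits[2, 1], hits[2, 2]))
    }
    if (nrow(hits) == 1L) {
      labels[[.MARKER_LABELS[[marker]]]] <- state_at[hits[1, 1], hits[1, 2]]
    }
  }

  neighbors <- matrix(0L, n_states, 4L,
                      dimnames = list(NULL, names(ACTIONS)[1:4]))
  for (s in seq_len(n_states)) {
    x <- coords[s, 1]; y <- coords[s, 2]
    for (a in 1:4) {
      nx <- x + .ACTION_DELTA[a, 1]; ny <- y + .ACTION_DELTA[a, 2]
      if (nx >= 0L && nx < width && ny >= 0L && ny < height &&
          open_mask[ny + 1L, nx + 1L]) {
        neighbors[s, a] <- state_at[ny + 1L, nx + 1L]
      }
    }
  }

  # reward-marker cells are terminal "reward sites" from the outset: their
  # only action is collect, initially worth 0, until a protocol raises it
  terminal <- rep(FALSE, n_states)
  for (lab in intersect(c("R", "R1", "R2"), names(labels))) {
    terminal[labels[[lab]]] <- TRUE
  }

  structure(
    list(width = width, height = height, n_states = n_states,
         coords = coords, state_at = state_at, neighbors = neighbors,
         open = rep(TRUE, n_states), rewards = numeric(n_states),
         terminal = terminal, labels = labels),
    class = "gridworld")
}

#' Read a gridworld map from a file
#'
#' @param path Path to an ASCII map file.
#' @return A `gridworld` object.
#' @seealso [parse_grid_map()], [task_map()]
#' @export
read_grid_map <- function(path) {
  parse_grid_map(readLines(path))
}

#' Locate a bundled task map
#'
#' The package ships compact maze fixtures reproducing the topological
#' structure of the three revaluation tasks (latent learning, detour, policy
#' revaluation) plus a small acquisition maze. These are synthetic layouts:
#' they preserve each task's structure (start markers, reward sites, barrier
#' on the trained path, longer alternate corridor, large late reward in the
#' bottom-right corner) at a size chosen for fast repeated simulation.
#'
#' @param name One of `"latent"`, `"detour"`, `"policy_reval"`,
#'   `"acquisition"`.
#' @return For `task_map_file`, the file path; for `task_map`, the parsed
#'   `gridworld`.
#' @export
task_map_file <- function(name = c("latent", "detour", "policy_reval",
                                   "acquisition")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".map"), package = "gridsr",
              mustWork = TRUE)
}

#' @rdname task_map_file
#' @export
task_map <- function(name = c("latent", "detour", "policy_reval",
                              "acquisition")) {
  read_grid_map(task_map_file(name))
}

#' Resolve a cell reference to a state index
#'
#' Cells may be referred to by state index, by label name (e.g. `"R1"`), or
#' by 0-based `c(x, y)` coordinates.
#'
#' @param world A `gridworld`.
#' @param cell State index, label string, or length-2 coordinate vector.
#' @return Integer state index.
#' @export
state_index <- function(world, cell) {
  if (is.character(cell)) {
    if (!cell %in% names(world$labels)) {
      stop(sprintf("no label '%s' in this map", cell))
    }
    return(world$labels[[cell]])
  }
  cell <- as.integer(cell)
  if (length(cell) == 2L) {
    s <- world$state_at[cell[2] + 1L, cell[1] + 1L]
    if (is.na(s)) stop(sprintf("cell (%d,%d) is a wall", cell[1], cell[2]))
    return(s)
  }
  if (cell < 1L || cell > world$n_states) stop("state index out of range")
  cell
}

#' Available actions in a state
#'
#' A reward site (any rewarded cell, including a zero-magnitude site) offers
#' exactly the `collect` action. Any other open cell offers the cardinal
#' moves whose target cell is open and in bounds, in the fixed order N, E, S,
#' W. Blocked moves are unavailable rather than no-ops: agents select among
#' available actions only.
#'
#' @param world A `gridworld`.
#' @param s State reference (see [state_index()]).
#' @return Named integer vector of action codes (subset of [ACTIONS]).
#' @export
available_actions <- function(world, s) {
  s <- state_index(world, s)
  if (!world$open[s]) return(ACTIONS[0])
  if (world$terminal[s]) return(ACTIONS["collect"])
  a <- which(world$neighbors[s, ] > 0L & world$open[pmax(world$neighbors[s, ], 1L)])
  ACTIONS[a]
}

#' Take one deterministic environment step
#'
#' Cardinal moves go to the adjacent open cell with zero reward; `collect`
#' yields the cell's reward and transitions to the absorbing terminal
#' pseudo-state (`s_next = NA`). Reward is emitted only on `collect` and
#' always co-occurs with termination. Attempting an unavailable action is an
#' error: agents must never select one.
#'
#' @param world A `gridworld`.
#' @param s State reference.
#' @param action Action code or name.
#' @return A list with elements `s`, `action`, `reward`, `s_next`
#'   (`NA_integer_` when terminal), `terminal`.
#' @export
world_step <- function(world, s, action) {
  s <- state_index(world, s)
  if (is.character(action)) action <- ACTIONS[[action]]
  action <- as.integer(action)
  avail <- available_actions(world, s)
  if (!action %in% avail) {
    stop(sprintf("action %s unavailable in state %d",
                 names(ACTIONS)[action], s))
  }
  if (action == ACTIONS[["collect"]]) {
    list(s = s, action = action, reward = world$rewards[s],
         s_next = NA_integer_, terminal = TRUE)
  } else {
    list(s = s, action = action, reward = 0,
         s_next = unname(world$neighbors[s, action]), terminal = FALSE)
  }
}

#' Set the reward magnitude of a cell
#'
#' Placing a positive reward collapses the cell's available actions to
#' `collect`; the cell becomes episode-terminating. Setting a zero reward on
#' an unrewarded cell is a no-op. State indexing is unchanged.
#'
#' @param world A `gridworld`.
#' @param cell Cell reference.
#' @param magnitude Reward value, `>= 0`.
#' @return The modified `gridworld`.
#' @export
set_reward <- function(world, cell, magnitude) {
  s <- state_index(world, cell)
  if (!world$open[s]) stop("cannot place a reward on a wall cell")
  if (!is.numeric(magnitude) || length(magnitude) != 1L || magnitude < 0) {
    stop("reward magnitude must be a single nonnegative number")
  }
  if (magnitude == 0 && !world$terminal[s]) return(world)  # no-op
  world$rewards[s] <- magnitude
  if (magnitude > 0) world$terminal[s] <- TRUE
  world
}

#' Convert an open cell into a wall
#'
#' The cell is removed from the open set and its neighbours' available action
#' sets shrink accordingly, but it keeps its state index (with an empty
#' action set) so that agents' matrices retain fixed dimensions across the
#' manipulation. Rewarded cells cannot be walled off.
#'
#' @param world A `gridworld`.
#' @param cell Cell reference.
#' @return The modified `gridworld`.
#' @export
insert_wall <- function(world, cell) {
  s <- state_index(world, cell)
  if (!world$open[s]) stop("cell is already a wall")
  if (world$terminal[s]) stop("cannot wall off a reward site")
  world$open[s] <- FALSE
  world
}

#' Breadth-first shortest-path distances to a goal cell
#'
#' Distances are step counts over cardinal moves; unreachable states get
#' `Inf`. Rewarded cells other than the goal are treated as non-traversable,
#' because entering one ends the episode (its only action is `collect`).
#'
#' @param world A `gridworld`.
#' @param goal Goal cell reference (must be open).
#' @return Numeric vector of length `n_states`; `Inf` for unreachable or
#'   walled states.
#' @export
shortest_path_distances <- function(world, goal) {
  g <- state_index(world, goal)
  if (!world$open[g]) stop("goal is a wall")
  d <- rep(Inf, world$n_states)
  d[g] <- 0
  queue <- g
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (a in 1:4) {
      nb <- world$neighbors[cur, a]
      if (nb > 0L && world$open[nb] && is.infinite(d[nb]) &&
          (!world$terminal[nb] || nb == g)) {
        d[nb] <- d[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  d
}

#' @export
print.gridworld <- function(x, ...) {
  cat(sprintf("<gridworld %dx%d, %d states (%d open)>\n",
              x$width, x$height, x$n_states, sum(x$open)))
  glyph <- matrix("#", x$height, x$width)
  for (s in seq_len(x$n_states)) {
    ch <- if (!x$open[s]) "#" else if (x$rewards[s] > 0) "$" else
      if (x$terminal[s]) "o" else "."
    glyph[x$coords[s, 2] + 1L, x$coords[s, 1] + 1L] <- ch
  }
  for (lab in names(x$labels)) {
    s <- x$labels[[lab]]
    if (x$open[s] && !x$terminal[s]) {
      glyph[x$coords[s, 2] + 1L, x$coords[s, 1] + 1L] <-
        substr(lab, nchar(lab), nchar(lab))
    }
  }
  cat(apply(glyph, 1, paste, collapse = ""), sep = "\n")
  if (length(x$labels)) {
    cat("labels:", paste(sprintf("%s=%d", names(x$labels), x$labels),
                         collapse = " "), "\n")
  }
  invisible(x)
}

# Pack a gridworld into the plain-list form consumed by the C++ engine.
.world_compiled <- function(world) {
  list(n_states = world$n_states,
       neighbors = world$neighbors,
       open = world$open,
       terminal = world$terminal,
       rewards = world$rewards)
}
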