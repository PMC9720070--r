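# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0

# UUID-derived "2.25.<decimal>" DICOM UIDs. A private counter plus
# clock-seeded digits keep UIDs unique without touching the caller's RNG
# stream, so exports never perturb simulation reproducibility.
.uid_state <- new.env(parent = emptyenv())
.uid_state$counter <- 0L

uid_generate <- function() {
  .uid_state$counter <- .uid_state$counter + 1L
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed((as.integer(Sys.time()) %% 1000000L) * 1000L +
             Sys.getpid() %% 1000L + .uid_state$counter)
  digits <- sample.int(10L, 28L, replace = TRUE) - 1L
  digits[1] <- sample.int(9L, 1L)
  paste0("2.25.", paste(digits, collapse = ""),
         sprintf("%04d", .uid_state$counter %% 10000L))
}
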