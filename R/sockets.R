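#' Serve a brain over the ASCII socket protocol
#'
#' The brain side of the world/brain coupling: listens on a TCP port,
#' accepts one world connection, and for every `"SENSE ..."` line advances
#' the network `steps_per_message` timesteps and replies with a
#' `"MOTOR l r"` line. Payloads are a few tens of bytes each way. The
#' server returns when the client disconnects or sends `"BYE"`.
#'
#' @param port TCP port to listen on.
#' @param controller A controller built on this side (usually
#'   [neural_controller()]); its `step()` receives the decoded
#'   concentrations with proximity `Inf` (the protocol carries
#'   concentrations only).
#' @param steps_per_message Neural timesteps per SENSE message.
#' @param max_messages Safety bound on messages served.
#' @param timeout Seconds to wait for a connection.
#' @return Number of messages served, invisibly.
#' @export
serve_brain <- function(port, controller, steps_per_message = 4L,
                        max_messages = Inf, timeout = 30) {
  stopifnot(inherits(controller, "pb_controller"))
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  con <- socketAccept(srv, blocking = TRUE, open = "r+b", timeout = timeout)
  on.exit(close(con), add = TRUE)
  controller$reset()
  served <- 0
  while (served < max_messages) {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || identical(trimws(line), "BYE")) break
    conc <- decode_sense_message(line)
    cmd <- controller$step(conc, Inf, steps_per_message)
    writeLines(sub("\n$", "", encode_motor_message(cmd[1], cmd[2])), con)
    flush(con)
    served <- served + 1
  }
  invisible(served)
}

#' Controller that forwards sensing over a socket
#'
#' The world side of the socket coupling: a drop-in controller for
#' [run_trial()] that encodes each concentration sample as a SENSE line,
#' sends it to a remote brain (see [serve_brain()]) and decodes the MOTOR
#' reply. Because [run_trial()] quantizes in-process controller input
#' through the same protocol, socket and in-process couplings of the same
#' brain produce identical trial results.
#'
#' @param host,port Address of the serving brain.
#' @param timeout Seconds to wait for the connection.
#' @return A controller object; call `$close()` when done.
#' @export
socket_controller <- function(host = "127.0.0.1", port, timeout = 30) {
  con <- socketConnection(host, port, blocking = TRUE, open = "r+b",
                          timeout = timeout)
  step <- function(concentrations, prox, n_substeps = 4L) {
    writeLines(sub("\n$", "", encode_sense_message(concentrations)), con)
    flush(con)
    line <- readLines(con, n = 1)
    if (length(line) == 0)
      stop("protocol error: brain closed the connection", call. = FALSE)
    decode_motor_message(line)
  }
  close_fn <- function() {
    try(writeLines("BYE", con), silent = TRUE)
    try(flush(con), silent = TRUE)
    try(close(con), silent = TRUE)
    invisible(NULL)
  }
  structure(list(reset = function() invisible(NULL), step = step,
                 close = close_fn, kind = "socket"),
            class = "pb_controller")
}
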