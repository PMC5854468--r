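# Shared in-code fixtures: all geometry is generated, nothing is stored.

make_circle <- function(radius = 1, n = 128, pixel_size = 0.065) {
  generate_contour(contour_scenario("sphere", radius = radius,
                                    n_vertices = n),
                   pixel_size = pixel_size)
}

make_rod <- function(width = 1, length = 4, n = 200) {
  generate_contour(contour_scenario("rod", width = width, length = length,
                                    n_vertices = n))
}

# axis-aligned rectangle as a raw contour (many vertices per side so the
# principal-axis mesh has chords to intersect)
make_rectangle <- function(L = 4, w = 1, per_side = 40) {
  sx <- seq(-L / 2, L / 2, length.out = per_side)
  sy <- seq(-w / 2, w / 2, length.out = per_side)
  x <- c(sx, rep(L / 2, per_side - 2L), rev(sx), rep(-L / 2, per_side - 2L))
  y <- c(rep(-w / 2, per_side), sy[2:(per_side - 1L)], rep(w / 2, per_side),
         rev(sy[2:(per_side - 1L)]))
  cell_contour(x, y)
}

rotate_contour <- function(contour, angle_deg) {
  th <- angle_deg * pi / 180
  cell_contour(contour$x * cos(th) - contour$y * sin(th),
               contour$x * sin(th) + contour$y * cos(th),
               pixel_size = contour$pixel_size)
}

# straight track at a given axial angle (degrees)
make_line_track <- function(angle_deg = 30, n = 20, step = 0.05, id = "t",
                            x0 = 0, y0 = 0, dt = 1) {
  th <- angle_deg * pi / 180
  s <- (seq_len(n) - 1L) * step
  track(id, seq_len(n), x0 + s * cos(th), y0 + s * sin(th), dt)
}
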