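# Physical constants and unit helpers used across the package.
# Internal time unit is the hour; lengths are metres unless a function
# documents nm; amounts are molecule counts; concentrations mol/m^3
# (numerically equal to mM).

.AVOGADRO <- 6.02214076e23

.NM2_TO_M2 <- 1e-18
.NM_TO_M <- 1e-9

# seconds -> hours conversion factor for permeabilities stored in m/s
.PER_S_TO_PER_H <- 3600

.sphere_area <- function(r) 4 * pi * r^2
.sphere_volume <- function(r) 4 / 3 * pi * r^3
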