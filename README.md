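# peppytwin

A pure-software digital twin of a tangible, modular and articulated
coarse-grained peptide interface: a set of 3D-printed, magnet-jointed
molecular modules (methyl, amide, alpha-carbon, C-/N-terminal caps)
instrumented with wireless angle sensors, whose manipulations drive a
virtual molecular avatar in real time. `peppytwin` re-implements the
whole software side of such an interface — the articulated molecular
model *and* the embedded device layer — so the system can be studied,
tested and extended without any hardware.

It is intended for researchers in structural bioinformatics and
human–machine interaction who want to prototype tangible molecular
interfaces, and for anyone who needs a fully scriptable, deterministic
simulation of the interface's protocols.

## What it models

**Articulated chain model.** Each physical module is a rigid body with
one to three junction faces; a junction is a single-axis pivot, so a
chain is a kinematic tree. Connections obey the chemistry of the
underlying coarse-grained model: methyl and the terminal caps plug only
into an alpha-carbon, and an amide plugs into an alpha-carbon by either
its C or its N face. Geometry lives in the left-handed, Y-up frame
(`x = ρ cosθ sinφ, y = ρ cosφ, z = ρ sinθ sinφ`), and the whole scene is
a dictionary of parts keyed by unique ID, supporting several sub-chains,
disconnection of any subtree and its recursive reconnection.

**Device layer.** Faithful discrete-time simulations of:

- the 14-bit hall-effect angle sensor (raw codes, per-board magnet
  offset correction, plug detection at a strict 4000-unit field
  threshold);
- the infrared pairing handshake between freshly plugged parts —
  START + 8-bit master ID + STOP + 4 dead bits + START + 16 reply bits +
  STOP = 32 bit-periods = **32 ms** at the 1 ms bit period (125 µs timer
  ticks, 8 per bit), including the per-tick Rx/Tx automatons;
- the wireless node network: static 5-ary tree (3125 = 5^5 addressable
  modules per channel) and dynamic rerouting topology (254 node IDs,
  immune to sudden death), gateway routing, broadcast, node ID
  allocation strategies, and over-the-air firmware paging in 16-byte
  pages with a 4 s watchdog.

Scenes are built interactively, from `.pusmol` scripts (a plain-text
command language that records every valid command), or procedurally; any
scene exports to standard PDB at the physical model's scale of 1 Å :
18.7 mm.

## Worked example

```r
library(peppytwin)

# procedurally generate and build a 2-residue backbone
ses <- run_script(make_backbone(2, seed = 1))
print(ses$scene)
#> <scene> 7 part(s), 1 sub-chain(s)
#>   [1] ALPHA_CARBON (root)
#>   [2] N_TERM <- parent 1 face 0, angle 95.58312 deg
#>   [3] METHYL <- parent 1 face 2, angle 133.9646 deg
#>   [4] AMIDE <- parent 1 face 1, angle 206.2272 deg
#>   [5] ALPHA_CARBON <- parent 4 face 1, angle 326.9548 deg
#>   [6] METHYL <- parent 5 face 2, angle 72.6055 deg
#>   [7] C_TERM <- parent 5 face 1, angle 323.4203 deg
```

Seven parts: two residues (alpha-carbon + methyl side chain each) joined
by one amide, capped at both ends, every joint at a random absolute
angle. Export it at the physical scale — model millimetres divided by
18.7 give Ångström:

```r
pdb <- export_structure(ses$scene, scale_mm_per_angstrom = 18.7)
cat(head(pdb, 3), sep = "\n")
#> ATOM      1  CA  CAL A   1       0.000   0.000  -0.000  1.00  0.00           C
#> ATOM      2  H   CAL A   1      -0.629  -0.629  -0.629  1.00  0.00           H
#> ATOM      3  N   NTR A   2       0.840   0.840  -0.840  1.00  0.00           N
```

The N-terminal nitrogen sits at (0.840, 0.840, −0.840) Å, i.e. 1.455 Å
from the alpha-carbon — the Cα–N bond length of the template geometry.
Simulate the pairing handshake that would fire when two parts are
plugged together:

```r
run_pairing(42, 7)
#> <pairing_session> master 42 <-> slave 7 | SUCCESS in 1 attempt(s), 32 ms per handshake
```

The slave echoed check-ID 42 (the master's own ID), so pairing
succeeded; the handshake always spans 32 bit-periods of 1 ms. A
command-line front end wrapping these functions is installed under
`exec/peppytwin` (subcommands `build`, `export`, `interactive`,
`simulate-stream`, `simulate-net`, `pair`).

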