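# Minimal residue-level heavy-atom charge / Lennard-Jones table.
# Hydrogens are implicit: each hydrogen's charge is folded into its parent
# heavy atom, so per-residue sums equal the formal charge at pH 7
# (Asp/Glu -1, Lys/Arg +1, His 0, all others 0).
# atom_name "*" is the per-residue fallback entry.
# lj_epsilon in kcal/mol, lj_rmin_half in Angstrom.
residue_name,atom_name,charge,lj_epsilon,lj_rmin_half
ALA,*,0.0,0.07,2.0
ARG,*,0.0,0.07,2.0
ARG,NH1,0.5,0.20,1.85
ARG,NH2,0.5,0.20,1.85
ASN,*,0.0,0.07,2.0
ASP,*,0.0,0.07,2.0
ASP,OD1,-0.5,0.12,1.70
ASP,OD2,-0.5,0.12,1.70
CYS,*,0.0,0.07,2.0
GLN,*,0.0,0.07,2.0
GLU,*,0.0,0.07,2.0
GLU,OE1,-0.5,0.12,1.70
GLU,OE2,-0.5,0.12,1.70
GLY,*,0.0,0.07,2.0
HIS,*,0.0,0.07,2.0
ILE,*,0.0,0.07,2.0
LEU,*,0.0,0.07,2.0
LYS,*,0.0,0.07,2.0
LYS,NZ,1.0,0.20,1.85
MET,*,0.0,0.07,2.0
PHE,*,0.0,0.07,2.0
PRO,*,0.0,0.07,2.0
SER,*,0.0,0.07,2.0
THR,*,0.0,0.07,2.0
TRP,*,0.0,0.07,2.0
TYR,*,0.0,0.07,2.0
VAL,*,0.0,0.07,2.0
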