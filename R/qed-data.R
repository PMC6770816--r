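# Definitions behind the weighted quantitative estimate of drug-likeness
# (QED): asymmetric desirability parameters, property weights, and the
# SMARTS vocabularies for acceptors, donors, rotatable bonds and the
# unwanted-substructure alert set. Values follow the published weighted
# QED scheme (Bickerton et al. desirability fits).

# Asymmetric double sigmoid parameters per property: a, b, c, d, e, f, dmax
.qed_ads_params <- list(
  MW = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD = c(1.618662227, 1010.051101, 0.985094388, 1e-09, 0.713820843, 0.920922555, 258.1632616),
  PSA = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB = c(0.01, 272.4121427, 2.55837997, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM = c(3.21778897, 957.7374108, 2.274627939, 1e-09, 1.317690384, 0.375760881, 312.337261),
  ALERTS = c(0.01, 1199.094025, -0.09002883, 1e-09, 0.185904477, 0.875193782, 417.725314)
)

# property weights of the weighted-mean QED variant
.qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# hydrogen-bond acceptor environments
.qed_acceptor_smarts <- c(
  "[oH0;X2]",
  "[OH1;X2;v2]",
  "[OH0;X2;v2]",
  "[OH0;X1;v2]",
  "[O-;X1]",
  "[SH0;X2;v2]",
  "[SH0;X1;v2]",
  "[S-;X1]",
  "[nH0;X2]",
  "[NH0;X1;v3]",
  "[$([N;+0;X3;v3]);!$(N[C,S]=O)]"
)

.qed_donor_smarts <- "[$([N;!H0;v3]),$([N;!H0;+1;v4]),$([O,S;H1;+0]),$([n;H1;+0])]"

# strict rotatable bond: non-ring single bond between non-terminal atoms,
# excluding triple-bond termini, CX3 halides, t-butyl and amide-like bonds
.qed_rotb_smarts <- "[!$(*#*)&!D1&!$(C(F)(F)F)&!$(C(Cl)(Cl)Cl)&!$(C(Br)(Br)Br)&!$(C([CH3])([CH3])[CH3])&!$([CD3](=[N,O,S])-!@[#7,O,S!D1])&!$([#7,O,S!D1]-!@[CD3]=[N,O,S])&!$([CD3](=[N+])-!@[#7!D1])&!$([#7!D1]-!@[CD3]=[N+])]-!@[!$(*#*)&!D1&!$(C(F)(F)F)&!$(C(Cl)(Cl)Cl)&!$(C(Br)(Br)Br)&!$(C([CH3])([CH3])[CH3])]"

# aromatic ring closure patterns by ring size (unique matches = ring count)
.arom_ring_smarts <- c("[aR]1[aR][aR][aR][aR]1",
                       "[aR]1[aR][aR][aR][aR][aR]1",
                       "[aR]1[aR][aR][aR][aR][aR][aR]1")

# unwanted-substructure alerts (counted as number of families triggered);
# two dot-disconnected families of the published set are expressed as count
# rules instead (>= 3 ester groups; >= 4 fluorine atoms), see .count_alerts()
.qed_alert_smarts <- c(
  "*1[O,S,N]*1",
  "[S,C](=[O,S])[F,Br,Cl,I]",
  "[CX4][Cl,Br,I]",
  "[#6]S(=O)(=O)O[#6]",
  "[$([CH]),$(CC)]#CC(=O)[#6]",
  "[$([CH]),$(CC)]#CC(=O)O[#6]",
  "n[OH]",
  "[$([CH]),$(CC)]#CS(=O)(=O)[#6]",
  "C=C(C=O)C=O",
  "n1c([F,Cl,Br,I])cccc1",
  "[CH1](=O)",
  "[#8][#8]",
  "[C;!R]=[N;!R]",
  "[N!R]=[N!R]",
  "[#6](=O)[#6](=O)",
  "[#16][#16]",
  "[#7][NH2]",
  "C(=O)N[NH2]",
  "[#6]=S",
  "[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]=[$([CH2]),$([CH][CX4]),$(C([CX4])[CX4])]",
  "C1(=[O,N])C=CC(=[O,N])C=C1",
  "C1(=[O,N])C(=[O,N])C=CC=C1",
  "a21aa3a(aa1aaaa2)aaaa3",
  "a31a(a2a(aa1)aaaa2)aaaa3",
  "a1aa2a3a(a1)A=AA=A3=AA=A2",
  "c1cc([NH2])ccc1",
  "[Hg,Fe,As,Sb,Zn,Se,se,Te,B,Si,Na,Ca,Ge,Ag,Mg,K,Ba,Sr,Be,Ti,Mo,Mn,Ru,Pd,Ni,Cu,Au,Cd,Al,Ga,Sn,Rh,Tl,Bi,Nb,Li,Pb,Hf,Ho]",
  "I",
  "OS(=O)(=O)[O-]",
  "[N+](=O)[O-]",
  "C(=O)N[OH]",
  "C1NC(=O)NC(=O)1",
  "[SH]",
  "[S-]",
  "c1ccc([Cl,Br,I,F])c([Cl,Br,I,F])c1[Cl,Br,I,F]",
  "c1cc([Cl,Br,I,F])cc([Cl,Br,I,F])c1[Cl,Br,I,F]",
  "[CR1]1[CR1][CR1][CR1][CR1][CR1][CR1]1",
  "[CR1]1[CR1][CR1]cc[CR1][CR1]1",
  "[CR2]1[CR2][CR2][CR2][CR2][CR2][CR2][CR2]1",
  "[CR2]1[CR2][CR2]cc[CR2][CR2][CR2]1",
  "[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1",
  "[CH2R2]1N[CH2R2][CH2R2][CH2R2][CH2R2][CH2R2][CH2R2]1",
  "C#C",
  "[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]@[CR2]@[CR2]@[OR2,NR2]",
  "[$([N+R]),$([n+R]),$([N+]=C)][O-]",
  "[#6]=N[OH]",
  "[#6]=NOC=O",
  "[#6](=O)[CX4,CR0X3,O][#6](=O)",
  "c1ccc2c(c1)ccc(=O)o2",
  "[O+,o+,S+,s+]",
  "N=C=O",
  "[NX3,NX4][F,Cl,Br,I]",
  "c1ccccc1OC(=O)[#6]",
  "[CR0]=[CR0][CR0]=[CR0]",
  "[C+,c+,C-,c-]",
  "N=[N+]=[N-]",
  "C12C(NC(N1)=O)CSC2",
  "c1c([OH])c([OH,NH2,NH])ccc1",
  "P",
  "[N,O,S]C#N",
  "C=C=O",
  "[Si][F,Cl,Br,I]",
  "[SX2]O",
  "[SiR0,CR0](c1ccccc1)(c2ccccc2)(c3ccccc3)",
  "O1CCCCC1OC2CCC3CCCCC3C2",
  "N=[CR0][N,n,O,S]",
  "[cR2]1[cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2][cR2]1[cR2]2[cR2][cR2][cR2]([Nv3X3,Nv4X4])[cR2][cR2]2",
  "C=[C!r]C#N",
  "[cR2]1[cR2]c([N+0X3R0,nX3R0])c([N+0X3R0,nX3R0])[cR2][cR2]1",
  "[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2]c([N+0X3R0,nX3R0])[cR2]1",
  "[cR2]1[cR2]c([N+0X3R0,nX3R0])[cR2][cR2]c1([N+0X3R0,nX3R0])",
  "[OH]c1ccc([OH,NH2,NH])cc1",
  "c1ccccc1OC(=O)O",
  "[SX2H0][N]",
  "c12ccccc1(SC(S)=N2)",
  "c12ccccc1(SC(=S)N2)",
  "c1nnnn1C=O",
  "s1c(S)nnc1NC=O",
  "S1C=CSC1=S",
  "C(=O)Onnn",
  "OS(=O)(=O)C(F)(F)F",
  "N#CC[OH]",
  "N#CC(=O)",
  "S(=O)(=O)C#N",
  "N[CH2]C#N",
  "C1(=O)NCC1",
  "S(=O)(=O)[O-,OH]",
  "NC[F,Cl,Br,I]",
  "C=[C!r]O",
  "[NX2+0]=[O+0]",
  "[OR0,NR0][OR0,NR0]",
  "[CX2R0][NX3R0]",
  "c1ccccc1[C;!R]=[C;!R]c2ccccc2",
  "[NX3R0,NX4R0,OR0,SX2R0][CX4][NX3R0,NX4R0,OR0,SX2R0]",
  "[s,S,c,C,n,N,o,O]~[n+,N+](~[s,S,c,C,n,N,o,O])(~[s,S,c,C,n,N,o,O])~[s,S,c,C,n,N,o,O]",
  "[s,S,c,C,n,N,o,O]~[nX3+,NX3+](~[s,S,c,C,n,N])~[s,S,c,C,n,N]",
  "[*]=[N+]=[*]",
  "[SX3](=O)[O-,OH]",
  "N#N",
  "[R0;D2][R0;D2][R0;D2][R0;D2]",
  "[cR,CR]~C(=O)NC(=O)~[cR,CR]",
  "C=!@CC=[O,S]",
  "[#6,#8,#16][#6](=O)O[#6]",
  "c[C;R0](=[O,S])[#6]",
  "c[SX2][C;!R]",
  "C=C=C",
  "c1nc([F,Cl,Br,I,S])ncc1",
  "c1ncnc([F,Cl,Br,I,S])c1",
  "c1nc(c2c(n1)nc(n2)[F,Cl,Br,I])",
  "[#6]S(=O)(=O)c1ccc(cc1)F",
  "[15N]",
  "[13C]",
  "[18O]",
  "[34S]"
)

.qed_ester_smarts <- "C(=O)O[C,H1]"

# surface-area contributions OpenBabel assigns to sulfur and phosphorus
# environments; subtracted to recover the nitrogen/oxygen-only polar
# surface area the QED desirability fits were trained on
.psa_sp_contrib <- c(
  "[#16X2H1]"   = 38.80,  # thiol
  "[#16X2H0;A]" = 25.30,  # aliphatic thioether/disulfide S
  "[#16X1]"     = 32.09,  # terminal =S
  "[#16X3;A]"   = 19.21,  # sulfoxide S
  "[#16X4]"     =  8.38,  # sulfone S
  "[s]"         = 28.24,  # aromatic S
  "[#15X3]"     = 13.59,  # trivalent P
  "[#15X4]"     =  9.81   # pentavalent P
)

# standard atomic weights (conventional, g/mol) for formula-based masses
.atomic_weights <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.18, Na = 22.99, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Ti = 47.867, Cr = 51.996, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, As = 74.922, Se = 78.971,
  Br = 79.904, Mo = 95.95, Ag = 107.87, Sn = 118.71, I = 126.9, Pt = 195.08,
  Au = 196.97, Hg = 200.59
)
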