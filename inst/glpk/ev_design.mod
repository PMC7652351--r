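# Team-orienteering integer linear program for epitope vaccine design.
#
# Vertex 0 is the polypeptide terminus; vertices 1..nv are epitopes.
# Each of the nt tours is a simple closed walk through the terminus; tours
# may only share the terminus. Miller-Tucker-Zemlin node potentials
# eliminate subtours. Side constraints enforce minimum pathogen coverage,
# minimum MHC-allele coverage, and minimum average epitope conservation.

param nv, integer, >= 1;           # number of epitopes
param nt, integer, >= 1;           # number of tours (polypeptides)
param ns, integer, >= 1;           # number of pathogen sequences
param na, integer, >= 1;           # number of MHC alleles

set V := 1..nv;
set V0 := 0..nv;
set T := 1..nt;
set S := 1..ns;
set A := 1..na;

param w{i in V0, j in V0: i != j};    # edge weights (design dependent)
param reward{V} >= 0;                 # sum_a p_a i_va per epitope
param conscount{V} >= 0;              # pathogens containing each epitope
param tau_s{V, S}, binary, default 0; # epitope-pathogen incidence
param tau_a{V, A}, binary, default 0; # epitope-allele binder indicators

param k, integer, >= 1;               # max epitopes per tour
param has_h, binary, default 0;       # per-tour edge-weight budget active?
param h, default 0;
param has_wmax, binary, default 0;    # bound on total edge weight, all tours
param wmax, default 0;
param has_imin, binary, default 0;    # lower bound on total immunogenicity
param imin, default 0;
param theta_s_min, >= 0, default 0;   # min pathogens covered
param theta_a_min, >= 0, default 0;   # min alleles covered
param gamma, >= 0, default 0;         # min avg conservation, scaled by ns

# Objective weights: immunogenicity, pathogen coverage, mean conservation,
# and a (usually small) penalty on the total edge weight used for the
# augmented epsilon-constraint sweep and for lexicographic cleavage solves.
param w_imm, default 1;
param w_cov, default 0;
param w_cons, default 0;
param w_cleav, default 0;

param umax := if nv > 1 then nv - 1 else 1;

var x{i in V0, j in V0, t in T: i != j}, binary;  # tour t uses edge (i,j)
var y{V, T}, binary;                              # tour t visits epitope v
var u{V, T}, integer, >= 1, <= umax;              # MTZ node potentials
var ts{S}, binary;                                # pathogen s covered
var ta{A}, binary;                                # allele a covered

maximize obj:
    w_imm  * sum{v in V, t in T} reward[v] * y[v,t]
  + w_cov  * sum{s in S} ts[s]
  + w_cons * sum{v in V, t in T} (conscount[v] / ns) * y[v,t]
  - w_cleav * sum{i in V0, j in V0, t in T: i != j} w[i,j] * x[i,j,t];

# C1: degree consistency between edge and vertex variables
s.t. c1_out{i in V, t in T}: sum{j in V0: j != i} x[i,j,t] = y[i,t];
s.t. c1_in {i in V, t in T}: sum{j in V0: j != i} x[j,i,t] = y[i,t];

# C4: every tour leaves from and returns to the terminus
s.t. c4_out{t in T}: sum{j in V} x[0,j,t] = 1;
s.t. c4_in {t in T}: sum{j in V} x[j,0,t] = 1;

# C2a: MTZ subtour elimination
s.t. c2a{i in V, j in V, t in T: i != j}:
    u[i,t] - u[j,t] + 1 <= (nv - 1) * (1 - x[i,j,t]);

# C3: tours may only share the terminus
s.t. c3{v in V}: sum{t in T} y[v,t] <= 1;

# C5: per-tour edge-weight budget (omitted when h is infinite)
s.t. c5{t in T: has_h == 1}:
    sum{i in V0, j in V0: i != j} w[i,j] * x[i,j,t] <= h;

# C6: per-tour vertex budget
s.t. c6{t in T}: sum{v in V} y[v,t] <= k;

# C7: pathogen coverage
s.t. c7a{s in S}: sum{v in V, t in T} tau_s[v,s] * y[v,t] >= ts[s];
s.t. c7b: sum{s in S} ts[s] >= theta_s_min;

# C8: allele coverage
s.t. c8a{a in A}: sum{v in V, t in T} tau_a[v,a] * y[v,t] >= ta[a];
s.t. c8b: sum{a in A} ta[a] >= theta_a_min;

# C9: minimum average epitope conservation
s.t. c9: sum{v in V, t in T} (conscount[v] - gamma) * y[v,t] >= 0;

# Optional bounds used by the epsilon-constraint sweep
s.t. c_wmax{z in 1..has_wmax}:
    sum{i in V0, j in V0, t in T: i != j} w[i,j] * x[i,j,t] <= wmax;
s.t. c_imin{z in 1..has_imin}:
    sum{v in V, t in T} reward[v] * y[v,t] >= imin;

solve;

printf "var,i,j,t\n" > "ev_solution.csv";
printf{t in T, i in V0, j in V0: i != j && x[i,j,t] > 0.5}
    "x,%d,%d,%d\n", i, j, t >> "ev_solution.csv";
printf{t in T, v in V: y[v,t] > 0.5} "y,%d,0,%d\n", v, t >> "ev_solution.csv";
printf{s in S: ts[s] > 0.5} "ts,%d,0,0\n", s >> "ev_solution.csv";
printf{a in A: ta[a] > 0.5} "ta,%d,0,0\n", a >> "ev_solution.csv";

end;
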