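# Default configuration of the epiastro simulator.
#
# Neural-mass constants (tau_ex .. Cu, eps) are the published model values.
# The astrocytic constants (lambda_a, k_ca, ca_th, kappa, mu_glu, eta_h) and
# the network coupling coefficient c_net are calibration constants: they were
# selected by the grid-search procedure described in the methods vignette so
# that the four discharge modes and the pre-treatment network signatures are
# reproduced.  kappa deliberately differs from 1 so that the mode-4 override
# (kappa = 1) is a genuine switch.

# neural-mass constants
tau_ex: 1.97
tau_in: 3.0
h_ex: -0.5
h_in: -1.4
C1: 1
C2: 15
C3: 6.1
Cu: 6
eps: 1000

# astrocyte coupling (calibrated)
lambda_a: 0.00358
k_ca: 230
ca_th: 198.95
kappa: 1.85
mu_glu: 1.83
eta_h: 9.4

# network coupling coefficient on a_ij f[Ex_j] (calibrated)
c_net: 0.205

# integration grid (time is in nominal milliseconds; the model is
# dimensionless, so these are simulation units)
dt: 0.05
t_total: 100

# network specification (n0 is the ring degree: two neighbours per side)
n_nodes: 50
n0: 4
p_rewire: 0.5
net_seed: 1

# mode-allocation scheme: stimulation (19/11/20) or surgery (20/8/2/20)
scheme: surgery

# stimulation (kind: none, random, sine, square)
stim_kind: none
stim_z: 0.1
stim_n: 0
stim_period: 10
stim_duty: 0.5
stim_seed: 1

# integrator: forward Euler on the output grid with n_sub substeps;
# the inhibitory relaxation uses an exact exponential update
method: euler
n_sub: 10
init: uniform
seed: 1
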