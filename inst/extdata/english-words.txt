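a
about
above
absence
absorption
abundance
accurate
acid
acids
activation
active
activity
acute
adaptive
addition
adhesion
adipose
adult
adverse
affect
after
age
aging
air
all
allele
alleles
also
alter
altered
among
amino
an
analysis
and
animal
animals
annotation
antibody
antigen
any
apoptosis
approach
are
area
array
arterial
artery
as
assay
assembly
assessment
association
at
atlas
autoimmune
average
axis
background
bacteria
bacterial
balance
based
baseline
be
because
been
before
behavior
between
binding
biology
biomarker
biopsy
birth
blood
body
bone
both
brain
breast
but
by
calcium
cancer
candidate
carbon
cardiac
care
case
cases
catalog
cell
cells
cellular
central
change
changes
characterization
chemical
child
children
cholesterol
chromatin
chromosome
chronic
circulating
classification
clinical
clone
cluster
cohort
collection
colon
combined
common
comparative
compare
comparison
complete
complex
component
composition
compound
concentration
condition
conditions
control
controls
core
correlation
cortex
count
coverage
culture
cycle
damage
daily
dataset
day
days
death
decrease
deep
default
deficiency
deletion
density
dependent
depression
derived
design
detection
development
developmental
diabetes
diagnosis
diet
dietary
differential
differentiation
digital
disease
diseases
disorder
distinct
distribution
diversity
division
dna
domain
dominant
dose
down
drug
drugs
during
dynamic
dynamics
each
early
effect
effects
efficacy
eight
elevated
embryo
embryonic
emergency
enhancer
environment
environmental
enzyme
epithelial
essential
estimate
evaluation
evidence
evolution
exercise
exome
experiment
experimental
exposure
expression
external
factor
factors
family
fasting
fat
feature
features
female
fetal
fiber
field
first
fish
five
flow
fluid
follow
following
food
for
form
formation
four
fraction
fragment
frequency
from
function
functional
fungal
gene
general
genes
genetic
genome
genomic
genomics
genotype
global
glucose
gradient
group
groups
growth
gut
has
have
health
healthy
heart
heat
height
hepatic
high
higher
histone
hormone
hospital
host
hour
hours
human
humans
hybrid
identification
identity
image
images
imaging
immune
immunity
impact
in
increase
increased
independent
index
individual
individuals
induced
infant
infection
inflammation
inflammatory
influence
information
inhibition
inhibitor
initial
injury
insulin
integration
interaction
interactions
internal
intestinal
into
invasive
is
isolated
isolation
its
joint
kidney
kinase
knockout
label
laboratory
large
late
lateral
lean
learning
left
length
lesion
level
levels
library
lifestyle
ligand
light
like
line
lines
linkage
lipid
liver
local
location
locus
long
longitudinal
loss
low
lower
lung
lymph
machine
magnetic
major
male
mammalian
map
mapping
marker
markers
mass
maternal
matrix
mature
mean
measure
measurement
measures
mechanism
median
mediated
medical
medicine
membrane
memory
metabolic
metabolism
metabolite
metadata
method
methods
methylation
mice
microbiome
microscopy
migration
minimal
minor
mitochondrial
model
models
moderate
modification
molecular
molecule
monitoring
month
months
morphology
mortality
motif
motor
mouse
multiple
muscle
mutant
mutation
mutations
national
native
natural
negative
nerve
network
neural
neuron
neurons
new
nine
nitrogen
no
node
normal
not
novel
nuclear
nucleotide
number
nutrient
obesity
observed
of
old
on
one
only
onset
open
or
oral
organ
organism
other
outcome
outcomes
over
overall
oxidative
oxygen
pain
paired
pancreatic
panel
parallel
parent
partial
pathogen
pathology
pathway
pathways
patient
patients
pattern
patterns
pediatric
peptide
performance
period
peripheral
phase
phenotype
phenotypes
physical
physiological
pilot
placebo
plasma
plant
point
polymorphism
pool
population
populations
positive
post
potential
predict
prediction
pregnancy
presence
pressure
prevalence
prevention
primary
primate
prior
probe
process
processes
production
profile
profiles
profiling
prognosis
programs
progression
project
promoter
prospective
protein
proteins
proteome
protocol
public
pulmonary
quality
quantitative
random
randomized
range
rare
rat
rate
ratio
rats
receptor
recombinant
record
recovery
reduced
reduction
reference
region
regions
regression
regulation
regulatory
related
relative
release
renal
repair
repeat
replicate
replication
report
repository
research
resistance
resistant
resolution
response
responses
resting
result
results
retinal
review
right
risk
rna
safety
saliva
sample
samples
scale
scan
score
screen
screening
second
secondary
section
selection
sensitivity
sequence
sequencing
serum
set
seven
severe
severity
sex
shared
short
signal
signaling
signature
single
site
sites
six
size
skeletal
skin
sleep
small
smoking
social
specific
spectrometry
spectrum
spinal
stability
stable
stage
standard
state
states
status
stem
stimulation
strain
strains
stress
stroke
structural
structure
structures
study
subject
subjects
subset
substrate
subtype
surface
surgery
survey
survival
susceptibility
symptom
symptoms
syndrome
synthesis
system
systematic
systems
target
targeted
targets
temperature
temporal
ten
term
tertiary
test
testing
that
the
therapeutic
therapy
this
three
through
time
timing
tissue
tissues
to
tolerance
total
toxicity
tract
training
trait
traits
transcript
transcription
transcriptome
transfer
transgenic
transition
translation
transplant
treated
treatment
trial
trials
tumor
tumors
two
type
types
under
unique
untreated
up
uptake
urinary
urine
use
using
validation
value
values
variable
variant
variants
variation
vascular
vector
vehicle
vein
ventricular
vertebrate
vessel
viral
virus
visual
vital
vitamin
vivo
vitro
volume
was
water
wave
weight
were
wheat
when
which
white
whole
wide
wild
with
within
without
year
years
yeast
yield
young
zebrafish
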