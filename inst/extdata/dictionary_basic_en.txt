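# Compact common-English word list used as the default dictionary veto for
# drug-compound classification. A replaceable snapshot: point the lexicon at a
# full US-English word list for production runs.
about
above
absence
accept
access
account
accurate
acid
across
action
active
activity
acute
add
adhesion
adult
advance
adverse
affect
after
again
against
age
agent
ago
agree
air
all
allow
almost
alone
along
already
also
although
always
among
amount
analysis
angle
animal
annual
another
answer
any
appear
apply
approach
area
argue
arm
around
arrive
artery
article
ask
assess
associate
assume
attack
attempt
author
available
average
avoid
away
back
bad
balance
band
base
basic
basis
bear
beat
because
become
bed
before
begin
behavior
behind
believe
belong
below
benefit
best
better
between
beyond
big
bind
biology
birth
bit
black
bleed
blind
block
blood
blue
board
body
bone
book
both
box
brain
branch
break
breath
bridge
brief
bring
broad
brother
build
burden
burn
business
call
can
cancer
candidate
capacity
carbon
card
care
carry
case
catch
cause
cell
center
central
certain
chain
chair
challenge
chance
change
chapter
character
charge
check
chest
child
choice
choose
chronic
circle
city
claim
class
clean
clear
clinic
clinical
close
cloud
coat
code
cold
collect
college
color
combat
combine
come
common
community
company
compare
complete
complex
compound
concern
conclude
condition
conduct
confirm
consider
consist
contain
content
context
continue
control
copy
core
corner
correct
cost
could
count
country
course
cover
create
critical
cross
crowd
culture
current
cut
cycle
daily
damage
dark
data
date
daughter
day
dead
deal
death
decade
decide
decline
decrease
deep
defect
define
degree
delay
deliver
demand
density
depend
depth
describe
design
despite
detail
detect
develop
device
diagnose
diet
differ
difference
difficult
direct
direction
discover
discuss
disease
disorder
distance
distinct
divide
doctor
dog
door
dose
double
down
draw
dream
drive
drop
drug
dry
due
early
earth
ease
east
easy
eat
edge
effect
effort
eight
either
element
eleven
else
emerge
employ
enable
end
energy
engage
enhance
enough
ensure
enter
entire
environment
equal
error
escape
essential
establish
estimate
evaluate
even
event
ever
every
evidence
exact
examine
example
exceed
except
exchange
exercise
exist
expand
expect
experience
expert
explain
explore
expose
express
extend
extent
external
extra
eye
face
fact
factor
fail
fall
false
family
far
fast
father
fear
feature
feed
feel
female
few
field
fifth
fight
figure
file
fill
film
final
find
fine
finger
finish
fire
first
fish
fit
five
fix
flat
floor
flow
fluid
focus
follow
food
foot
force
form
formal
format
former
forward
four
frame
free
frequency
frequent
fresh
friend
full
function
fund
further
future
gain
game
gas
gather
gene
general
generate
gentle
give
glass
goal
good
govern
grade
gradual
grant
great
green
ground
group
grow
growth
guano
guard
guess
guide
hand
happen
hard
harm
have
head
health
hear
heart
heat
heavy
height
help
hence
here
high
history
hold
hole
home
hope
hospital
host
hot
hour
house
however
human
hundred
idea
identify
image
imaging
impact
important
improve
include
income
increase
indeed
index
indicate
individual
induce
infant
infection
influence
inform
initial
injury
inner
input
inside
instead
intend
intense
interest
internal
interval
into
introduce
involve
iron
issue
item
join
joint
journal
judge
jump
just
keep
key
kidney
kind
know
label
labor
lack
land
language
large
last
late
later
laugh
launch
law
lead
learn
least
leave
left
leg
length
less
letter
level
lie
life
lift
light
like
likely
limit
line
link
lip
liquid
list
listen
little
live
liver
local
locate
long
look
lose
loss
low
lung
machine
main
maintain
major
make
male
manage
manner
many
map
mark
market
mass
match
material
matter
may
mean
measure
mechanism
media
medical
medicine
medium
meet
member
memory
mention
metal
method
middle
might
mild
million
mind
minor
minute
miss
mix
mixture
mode
model
moderate
modern
modify
moment
money
monitor
month
more
morning
most
mother
motion
mount
mouth
move
much
multiple
muscle
music
must
name
narrow
nation
native
nature
near
necessary
need
nerve
network
never
new
news
next
nice
night
nine
noise
none
normal
north
nose
note
nothing
notice
novel
now
number
nurse
object
observe
obtain
obvious
occur
ocean
odd
offer
office
often
old
once
one
only
onset
open
operate
opinion
option
order
organ
origin
other
outcome
output
outside
over
overall
own
oxygen
page
pain
paint
pair
panel
paper
parent
park
part
particular
partner
party
pass
past
path
patient
pattern
pause
pay
peace
peak
people
per
percent
perform
perhaps
period
person
phase
phone
physical
pick
picture
piece
place
plan
plane
plant
plasma
plate
platelet
play
please
point
policy
pool
poor
popular
population
position
positive
possible
post
potential
power
practice
predict
prefer
pregnant
prepare
presence
present
press
pressure
prevent
previous
price
primary
print
prior
private
probable
problem
procedure
process
produce
product
profile
program
progress
project
promote
proper
propose
protect
protein
prove
provide
public
publish
pull
pump
pure
purpose
push
put
quality
question
quick
quiet
quite
race
radio
raise
random
range
rapid
rare
rate
rather
ratio
reach
read
ready
real
reason
recent
recognize
record
recover
red
reduce
refer
reflect
regard
region
regular
relate
release
relevant
remain
remember
remove
repair
repeat
replace
report
represent
require
research
resource
respect
respond
response
rest
result
return
reveal
review
rich
ride
right
ring
rise
risk
road
rock
role
roll
room
root
rough
round
route
rule
run
safe
same
sample
save
scale
school
science
score
screen
sea
search
season
second
section
secure
see
seek
seem
select
self
sell
send
sense
series
serious
serve
service
set
settle
seven
severe
sex
shape
share
sharp
shift
shine
ship
short
should
show
side
sign
signal
similar
simple
since
single
sister
site
six
size
skill
skin
sleep
slight
slow
small
smooth
social
society
soft
solid
solution
solve
some
son
song
soon
sound
source
south
space
speak
special
specific
speed
spend
spite
split
spread
spring
square
stable
staff
stage
stand
standard
start
state
station
status
stay
steady
step
still
stock
stomach
stop
store
story
strain
strategy
stream
street
strength
stress
stretch
strict
strike
strong
structure
student
study
style
subject
success
such
sudden
suffer
suggest
suitable
summary
summer
supply
support
sure
surface
surgery
surround
survey
survive
sustain
switch
symptom
system
table
take
talk
target
task
teach
team
tell
ten
tend
term
test
text
than
thank
theme
then
theory
therapy
thick
thin
thing
think
third
thousand
three
thus
time
tissue
today
together
tone
tool
top
total
touch
toward
town
trace
track
trade
train
transfer
transport
travel
treat
treatment
tree
trend
trial
trigger
trouble
true
trust
truth
try
turn
twelve
twice
two
type
under
understand
unique
unit
until
update
upon
upper
use
useful
usual
value
variable
variant
various
vary
vast
vein
version
very
vessel
view
visible
vision
visit
vital
voice
volume
wait
walk
wall
want
warm
watch
water
wave
way
weak
wear
week
weight
welcome
well
west
wheel
when
where
whether
while
white
whole
wide
will
wind
window
winter
wish
within
without
woman
wonder
word
work
world
worry
worth
would
write
wrong
yard
year
yellow
yes
yet
yield
young
thermostat
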