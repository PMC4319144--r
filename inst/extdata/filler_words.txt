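about
above
across
after
again
against
almost
alone
along
already
although
always
among
anchor
ancient
animal
answer
anyone
anything
apartment
around
arrive
article
autumn
avenue
balance
balloon
banner
barely
basket
because
become
before
begin
behind
believe
below
beneath
beside
between
beyond
birthday
blanket
border
bottle
bottom
branch
breeze
bridge
bright
bring
brother
bucket
builder
bundle
butter
button
cabin
camera
candle
canvas
carpet
carry
castle
ceiling
cellar
center
certain
chance
change
chapter
charge
choose
cinema
circle
city
classic
clever
climb
closet
cloud
coast
coffee
collect
color
column
common
compass
contain
corner
cotton
country
course
cousin
cover
create
curtain
curve
cushion
dance
daughter
decide
degree
deliver
describe
desert
design
dinner
direction
discover
distance
double
dozen
dream
drive
during
early
earth
eastern
either
eleven
empty
engine
enough
evening
every
example
except
expect
explain
fabric
fairly
family
famous
fashion
feather
fellow
fence
festival
field
figure
finally
finger
finish
flavor
floor
flower
follow
forest
forget
fortune
forward
fountain
frame
friend
future
garden
gather
general
gentle
glass
golden
grammar
gravel
green
ground
guest
guitar
hammer
handle
happen
harbor
hardly
hello
herself
hidden
highway
hollow
honest
horizon
hotel
however
hundred
hungry
imagine
indeed
inside
instead
island
itself
jacket
journey
jungle
kettle
kitchen
ladder
landscape
language
lantern
large
laughter
leather
lesson
letter
little
lonely
lumber
machine
manner
marble
market
matter
meadow
measure
member
middle
million
mirror
moment
morning
mountain
movie
music
narrow
nation
nature
nearly
neighbor
neither
never
night
north
nothing
notice
number
object
ocean
office
often
orange
orchard
order
other
outside
over
paint
palace
paper
parade
parent
partner
pattern
pebble
pencil
people
perhaps
picture
pillow
planet
plant
plastic
pocket
point
porch
prairie
prepare
present
pretty
printer
project
promise
purple
puzzle
quarter
question
quiet
rabbit
rather
reason
remember
return
ribbon
river
rocket
round
saddle
sailor
school
season
second
secret
sentence
seven
shadow
shelter
shoulder
silent
silver
simple
singer
sister
smooth
soldier
someone
spring
square
station
story
street
student
subject
sudden
summer
sunset
supper
table
tailor
teacher
temple
theater
thirty
thought
thousand
through
thunder
timber
together
tomorrow
tonight
toward
travel
trouble
tunnel
turtle
twelve
twenty
under
until
upstairs
valley
velvet
village
violet
voyage
wagon
wander
weather
welcome
western
whisper
window
winter
wonder
wooden
yellow
yesterday
yonder
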