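# Synthetic content-word list (open-class filler vocabulary) for emovoc.
ally
alone
analyze
ancient
animal
answer
apple
arm
art
ask
asked
asking
asleep
ate
autumn
awake
baby
bag
ball
became
because
become
bed
began
begin
begun
believe
believed
best
better
big
bigger
bird
birth
black
blue
body
book
boring
bottom
bought
box
bread
break
breakfast
breaking
breath
bright
bring
bringing
broke
broken
brother
brought
brown
build
building
built
bus
busy
buy
buying
cake
call
called
calling
came
car
carried
carry
cat
certain
chair
chance
change
changed
chat
chatted
chatting
cheap
chicken
child
choice
church
city
class
clean
cleaned
cleaning
clear
clinic
clock
close
closed
closing
cloud
club
coat
coffee
cold
college
color
come
coming
common
computer
consider
cook
cooked
cooking
cool
cough
country
cow
cup
daily
dance
dark
day
death
decide
decided
deep
different
difficult
dinner
dirty
doctor
dog
dollar
door
drank
dream
dress
drink
drinking
drive
driven
driving
drove
dry
ear
early
easy
eat
eating
edge
empty
end
enough
evening
exercise
expensive
eye
face
faith
false
family
farm
fast
father
favorite
fever
few
field
find
finding
finish
finished
first
fish
fix
fixed
flat
flower
flu
food
foot
forest
forget
forgot
forgotten
found
free
fresh
friend
fruit
full
game
garden
gave
general
get
getting
gift
give
given
giving
glass
go
goal
god
going
gone
got
government
grass
gray
green
grew
group
grow
growing
grown
guest
habit
hair
half
hand
hard
hat
head
headache
health
hear
heard
hearing
heart
heat
heavy
held
help
helped
helping
high
history
hold
holding
holiday
home
horse
hospital
hot
hour
house
hungry
idea
illness
important
injury
interesting
internet
job
keep
keeping
kept
key
kingdom
kitchen
knew
know
knowing
known
land
large
last
late
law
leader
leaf
learn
learned
learning
leave
leaving
left
leg
lesson
letter
life
light
line
list
listen
listened
listening
little
live
lived
living
local
long
longer
look
looked
looking
loud
low
luck
lunch
made
mail
main
make
making
man
many
market
maybe
meat
medicine
meet
meeting
memory
message
met
middle
milk
mind
modern
money
month
moon
morning
mother
mountain
move
moved
movie
moving
music
narrow
nature
need
needed
neighbor
new
news
next
night
noise
normal
number
nurse
office
old
open
opened
opening
page
paid
pain
pair
paper
paperwork
parent
part
party
pay
paying
peace
pen
people
perhaps
person
phone
photo
picture
piece
pill
place
plan
plane
plant
plate
play
played
player
playing
point
poor
possible
price
private
project
public
put
putting
question
quick
quickly
quiet
radio
rain
rare
read
reading
ready
real
realize
reason
recent
red
reflect
remember
remembered
rest
result
rice
rich
ride
riding
right
river
road
rode
room
rough
round
rule
run
said
salt
sang
sat
saw
say
saying
school
science
screen
season
second
see
seed
seeing
seem
seemed
seen
sell
selling
send
sending
sent
several
sharp
sheep
shirt
shoe
shop
short
shorter
show
showed
showing
shown
sick
side
similar
simple
sing
singing
sister
sit
sitting
sky
sleep
slow
slowly
small
smaller
smooth
snow
social
soft
sold
song
sound
soup
sour
speak
speaking
special
spoke
sport
spring
square
stand
standing
star
start
started
starting
stay
stayed
staying
stood
stop
stopped
stopping
store
storm
story
street
strong
student
success
successful
sugar
summer
sun
swam
sweet
swim
swimming
table
take
taken
taking
talk
talked
talking
tall
task
taught
tea
teach
teacher
teaching
team
tell
telling
test
thing
think
thinking
third
thirsty
thought
time
tired
together
told
took
top
town
train
travel
tree
tried
trip
true
try
trying
turn
turned
turning
typical
understand
understood
use
used
useful
using
usual
visit
voice
wait
waited
waiting
walk
wall
want
wanted
wanting
war
warm
watch
watched
watching
water
way
weak
wear
wearing
weather
week
weekend
weekly
went
wet
white
whole
wide
win
wind
window
winning
winter
woman
won
wonder
word
wore
work
world
worn
worse
worst
write
writing
written
wrong
wrote
year
yellow
young
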